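{
  "ls_genes": ["MLH1", "MSH2", "MSH6", "PMS2", "EPCAM"],
  "hboc_genes": ["ATM", "BARD1", "BRCA1", "BRCA2", "BRIP1", "CDH1", "CHEK2", "NF1", "PALB2", "PTEN", "RAD51C", "RAD51D", "STK11", "TP53"],
  "candidate_genes": ["MUTYH", "FANCA", "POLE", "POLD1", "APC", "NBN", "AIP", "ALK", "ATR", "ATRIP", "AXIN1", "AXIN2", "BAP1", "BLM", "BMPR1A", "BRCC3", "BUB1B", "CASP8", "CDC73", "CDK4", "CDKN1B", "CDKN1C", "CDKN2A", "CEBPA", "CEP57", "CHEK1", "CTNNA1", "CYLD", "DDB2", "DICER1", "DIS3L2", "DCLRE1A", "DCLRE1B", "DCLRE1C", "EGFR", "ELAC2", "ERCC1", "ERCC2", "ERCC3", "ERCC4", "ERCC5", "ERCC6", "ERCC8", "EXO1", "EXT1", "EXT2", "EZH2", "FAN1", "FANCB", "FANCC", "FANCD2", "FANCE", "FANCF", "FANCG", "FANCI", "FANCL", "FANCM", "FBXW7", "FH", "FLCN", "GALNT12", "GATA2", "GEN1", "GPC3", "GREM1", "HNF1A", "HNF1B", "HOXB13", "HRAS", "KIF1B", "KIT", "LIG1", "LIG3", "LIG4", "MAX", "MCPH1", "MDC1", "MDM2", "MDM4", "MEN1", "MET", "MITF", "MLH3", "MRE11A", "MSH3", "MSH5", "MUS81", "NF2", "NHEJ1", "NSD1", "NTHL1", "OGG1", "PALLD", "PARP1", "PHOX2B", "PMS1", "POLB", "POLG", "POLH", "POLQ", "PPM1D", "PRF1", "PRKAR1A", "PTCH1", "PTCH2", "RAD1", "RAD17", "RAD18", "RAD23B", "RAD50", "RAD51", "RAD51B", "RAD52", "RAD54B", "RAD54L", "RAD9A", "RB1", "RBBP8", "RECQL", "RECQL4", "RECQL5", "RET", "RFC1", "RHBDF2", "RINT1", "RNASEL", "RPA1", "RUNX1", "SBDS", "SDHA", "SDHAF2", "SDHB", "SDHC", "SDHD", "SLX4", "SMAD4", "SMARCA4", "SMARCB1", "SMARCE1", "SUFU", "TERT", "TMEM127", "TOPBP1", "TP53BP1", "TSC1", "TSC2", "UIMC1", "VHL", "WRN", "WT1", "XPA", "XPC", "XRCC1", "XRCC2", "XRCC3", "XRCC4", "XRCC5", "XRCC6", "ABRAXAS1", "AKT1", "ANKRD26", "APEX1", "BRD7", "CDK12", "CDKN2B", "DDX41", "DKC1", "DOCK8", "DROSHA", "EME1", "EME2", "ERBB2", "ERBB3", "ETV6", "FAAP20", "FAAP24", "HELQ", "HFE", "HUS1", "KAT5", "LZTR1", "MAD2L2", "MMS19", "MPG", "NEIL1", "NEIL2", "NEIL3", "NSMCE2", "NUDT1", "PARP2", "PAXIP1", "PCNA", "PIF1", "PNKP", "POLD2", "POLE2", "POLI", "POLK", "POLL", "POLM", "POLN", "PRKDC", "RAD21", "RAD51AP1", "REV1", "REV3L", "RTEL1"]
}
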