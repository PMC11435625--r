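chemical_id,name,mol_wt,cf2,oecd_category,fup,clint,css_uM,pod_uM,aed_mg_per_kg_day
DTXSID6062599,PFPeA,263.98,4,PFCAs,0.0440,0,20.78,NA,NA
DTXSID5030030,PFBS,299.95,4,PFSAs,0.0128,4.75,7.51,6.22,0.83
DTXSID30891564,4:2 FTS,327.98,4,n:2 FTSAs,0.0050,4.28,19.12,NA,NA
DTXSID3031862,PFHxA,313.98,5,PFCAs,0.0068,0,113.04,9.06,0.08
DTXSID20874028,5:3 FTCA,342.01,5,n:3 acids,0.0059,11.84,6.18,6.10,0.99
DTXSID6067331,6:2 FTS,427.98,6,n:2 FTSAs,0.0143,1.4,12.36,11.02,0.89
DTXSID1037303,PFHpA,363.98,6,PFCAs,0.0004,0,1657.68,16.57,0.01
DTXSID70379917,6:3 FTCA,392.01,6,n:3 acids,0.0023,5.05,30.01,5.49,0.18
DTXSID70565479,8H-PFOA,395.98,6,1-H PFCAs,0.0021,0,290.23,10.59,0.04
DTXSID7040150,PFHxS,399.94,6,PFSAs,0.0009,0,670.49,22.38,0.033
DTXSID50226894,9H-PFNA,445.98,7,1-H PFCAs,0.0009,0,601.28,2.47,0.004
DTXSID8059920,PFHpS,449.94,7,PFSAs,0.0006,0,893.98,18.05,0.02
DTXSID90382620,7:3 FTCA,442.01,7,n:3 acids,0.0051,15.7,4.99,0.96,0.19
DTXSID8031865,PFOA,413.97,7,PFCAs,0.0010,0,582.99,8.07,0.01
DTXSID8031863,PFNA,463.97,8,PFCAs,0.0016,0,325.11,14.73,0.05
DTXSID3031864,PFOS,499.94,8,PFSAs,0.0049,0,98.52,8.02,0.08
DTXSID5061954,11H-PFUnDA,545.98,9,1-H PFCAs,0.0015,0,294.69,7.41,0.03
DTXSID3031860,PFDA,513.97,9,PFCAs,0.0027,0,173.91,10.89,0.06
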