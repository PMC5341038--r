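model,period,total_km2,low_km2,high_km2,overlap_km2
Present,present,534953,350488,184465,NA
Mid-Holocene-CCSM,Holocene,292256,131119,161137,271543
Mid-Holocene-MIROC,Holocene,408637,116960,291677,293095
Mid-Holocene-MPI,Holocene,444012,202967,241045,313977
LGM-CCSM,LGM,654131,283554,370577,471444
LGM-MIROC,LGM,605354,215318,390036,446446
LGM-MPI,LGM,696462,287786,408676,476104
2070-CCSM RCP 2.6,2070,362542,227309,135233,334527
2070-GFDL RCP 2.6,2070,194921,154649,40272,148629
2070-MPI RCP 2.6,2070,353095,262546,90549,336952
2070-CCSM RCP 8.5,2070,218920,138977,79943,164029
2070-GFDL RCP 8.5,2070,110608,89413,21195,50406
2070-MPI RCP 8.5,2070,141457,104742,36715,118065
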