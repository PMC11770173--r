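panel_id	members
erythrocyte	HBA1,HBA2,HBB,HBD,HBG1,HBG2,CA1,CA2,SLC4A1,SPTA1,SPTB,ANK1,PRDX2,BLVRB
cellular_debris	KRT1,KRT2,KRT5,KRT9,KRT10,KRT14,ACTB,ACTG1,TUBB,TUBA1B,GAPDH,VIM,LMNA,H4C1,HSPA8
serum_high_abundance	ALB,SERPINA1,TF,HP,HPX,IGHG1,IGHG2,IGHG3,IGHG4,IGKC,IGLC1,APOA1,APOA2,APOB,FGA,FGB,FGG,A2M,C3,ORM1
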