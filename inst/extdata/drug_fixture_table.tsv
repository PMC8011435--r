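name	inchikey	smiles	synonyms	drugbank	brd
Cyclobenzaprine	JURKNVYFZMSNLP-UHFFFAOYSA-N	CN(C)CCC=C1c2ccccc2C=Cc2ccccc21	Flexeril	DB00924	BRD-K42348709
Amitriptyline	KRMDCWKBEZIMAB-UHFFFAOYSA-N	CN(C)CCC=C1c2ccccc2CCc2ccccc21	Elavil	DB00321	BRD-K53737926
Imipramine	BCGWQEUPMDMJNV-UHFFFAOYSA-N	CN(C)CCCN1c2ccccc2CCc2ccccc21	Tofranil	DB00458	BRD-K38436528
Desipramine	HCYAFALTSJYZDH-UHFFFAOYSA-N	CNCCCN1c2ccccc2CCc2ccccc21	Norpramin	DB01151	BRD-K60762818
Diphenhydramine	ZZVUWRFHKOJYTH-UHFFFAOYSA-N	CN(C)CCOC(c1ccccc1)c1ccccc1	Benadryl	DB01075	BRD-K47278471
Lansoprazole	MJIHNNLFOKEZEW-UHFFFAOYSA-N	Cc1c(OCC(F)(F)F)ccnc1CS(=O)c1nc2ccccc2[nH]1	Prevacid	DB00448	BRD-A49172652
Rabeprazole	YREYEVIYCVEVJK-UHFFFAOYSA-N	COCCCOc1ccnc(CS(=O)c2nc3ccccc3[nH]2)c1C	Aciphex	DB01129	BRD-A39390670
Ropivacaine	ZKMNUMMKYBVTFN-HNNXBMFYSA-N	CCCN1CCCCC1C(=O)Nc1c(C)cccc1C	Naropin	DB00296	BRD-K50938786
Aminosalicylic acid	WUBBRNOQWQTFEX-UHFFFAOYSA-N	Nc1ccc(C(=O)O)c(O)c1	4-aminosalicylic acid|PAS	DB00233	BRD-K80267133
Mesalazine	KBOPZPXVLCULAV-UHFFFAOYSA-N	Nc1ccc(O)c(C(=O)O)c1	mesalamine|5-ASA	DB00244	BRD-K28849549
Flucytosine	XRECTZIEBJDKEO-UHFFFAOYSA-N	Nc1nc(=O)[nH]cc1F	5-fluorocytosine	DB01099	BRD-K82143716
Gabapentin	UGJMXCAKCUNAIE-UHFFFAOYSA-N	NCC1(CC(=O)O)CCCCC1	Neurontin	DB00996	BRD-K62737565
Enalapril	GBXSMTUPTTWBMN-XIRDDKMYSA-N	CCOC(=O)C(CCc1ccccc1)NC(C)C(=O)N1CCCC1C(=O)O	Vasotec	DB00584	BRD-K57545991
Atenolol	METKIMKYRPQLGS-LBPRGKRZSA-N	CC(C)NCC(O)COc1ccc(CC(N)=O)cc1	Tenormin	DB00335	BRD-K44993696
Dosulepin	PHTUQLWOUWZIMZ-GZTJUZNOSA-N	CN(C)CCC=C1c2ccccc2CSc2ccccc21	dothiepin	DB09167	BRD-K54759182
Doxepin	ODQWQRRAPPTVAG-BOPFTXTBSA-N	CN(C)CCC=C1c2ccccc2COc2ccccc21	Sinequan	DB01142	BRD-K37694030
Norcyclobenzaprine	XECQQDXTQRYYBH-UHFFFAOYSA-N	CNCCC=C1c2ccccc2C=Cc2ccccc21			BRD-K63165456
Tretinoin	SHGAZHPCJJPHSC-YCNIQYBTSA-N	CC1=C(C=CC(C)=CC=CC(C)=CC(=O)O)C(C)(C)CCC1	all-trans retinoic acid	DB00755	BRD-K64634304
Retinol	FPIPGXGPPPQFEQ-OVSJKPMPSA-N	CC1=C(C=CC(C)=CC=CC(C)=CCO)C(C)(C)CCC1	vitamin A	DB00162	BRD-K22429181
Camptothecin	VSJKWCGYPAHWDS-FQEVSTJZSA-N	CCC1(O)C(=O)OCC2=C1C=C1N(Cc3cc4ccccc4nc31)C2=O		DB04690	BRD-K37890730
Lapatinib	LTMKESNXUBQKBP-UHFFFAOYSA-N	CS(=O)(=O)CCNCc1ccc(-c2ccc3ncnc(Nc4ccc(OCc5cccc(F)c5)c(Cl)c4)c3c2)o1	Tykerb	DB01259	BRD-M07438658
Gatifloxacin	XUBOMFCQGDBHNK-UHFFFAOYSA-N	COc1c2c(cc(F)c1N1CCNC(C)C1)c(=O)c(C(=O)O)cn2C1CC1	Tequin	DB01044	BRD-A74980173
Secnidazole	KPQZUUQMTUIKBP-UHFFFAOYSA-N	CC(O)Cn1c(C)ncc1[N+](=O)[O-]	Solosec	DB12834	BRD-A70083328
Tocainide	BUJAGSGYPOAWEI-UHFFFAOYSA-N	CC(N)C(=O)Nc1c(C)cccc1C	Tonocard	DB01056	BRD-A92670106
Mevastatin	AJLFOPYRIVGYMJ-INTXDZFKSA-N	CCC(C)C(=O)OC1CCC=C2C=CC(C)C(CCC3CC(O)CC(=O)O3)C21	compactin		BRD-K94441233
Daunorubicin	STQGQHZAVUOBTE-INJOJONLSA-N	COc1cccc2c1C(=O)c1c(O)c3c(c(O)c1C2=O)CC(O)(C(C)=O)CC3OC1CC(N)C(O)C(C)O1	daunomycin	DB00694	BRD-K91966436
Aspirin	BSYNRYMUTXBXSQ-UHFFFAOYSA-N	CC(=O)Oc1ccccc1C(=O)O	acetylsalicylic acid|ASA	DB00945	
Caffeine	RYYVLZVUVIJVGH-UHFFFAOYSA-N	Cn1cnc2c1c(=O)n(C)c(=O)n2C	1,3,7-trimethylxanthine	DB00201	
Acetaminophen	RZVAJINKPMORJF-UHFFFAOYSA-N	CC(=O)Nc1ccc(O)cc1	paracetamol|Tylenol	DB00316	
Ibuprofen	HEFNNWSXXWATRW-UHFFFAOYSA-N	CC(C)Cc1ccc(C(C)C(=O)O)cc1	Advil|Motrin	DB01050	
Metformin	XZWYZXLIPXDOLR-UHFFFAOYSA-N	CN(C)C(=N)NC(=N)N	Glucophage	DB00331	
Warfarin	PJVWKTKQMONHTI-UHFFFAOYSA-N	CC(=O)CC(c1ccccc1)c1c(O)c2ccccc2oc1=O	Coumadin	DB00682	
Omeprazole	SUBDBMMJDZJVOS-UHFFFAOYSA-N	COc1ccc2[nH]c(S(=O)Cc3ncc(C)c(OC)c3C)nc2c1	Prilosec	DB00338	
Metoprolol	IUBSYMUCCVWXPE-UHFFFAOYSA-N	CC(C)NCC(O)COc1ccc(CCOC)cc1	Lopressor	DB00264	
Propranolol	AQHHHDLHHXJYJD-UHFFFAOYSA-N	CC(C)NCC(O)COc1cccc2ccccc12	Inderal	DB00571	
Ciprofloxacin	MYSWGUAQZAJSOK-UHFFFAOYSA-N	OC(=O)c1cn(C2CC2)c2cc(N3CCNCC3)c(F)cc2c1=O	Cipro	DB00537	
Fluoxetine	RTHCYVBBDHJXIQ-UHFFFAOYSA-N	CNCCC(Oc1ccc(C(F)(F)F)cc1)c1ccccc1	Prozac	DB00472	
Sertraline	VGKDLMBJGBXTGI-SJCJKPOMSA-N	CNC1CCC(c2ccc(Cl)c(Cl)c2)c2ccccc21	Zoloft	DB01104	
Diazepam	AAOVKJBEBIDNHE-UHFFFAOYSA-N	CN1c2ccc(Cl)cc2C(=NCC1=O)c1ccccc1	Valium	DB00829	
Lorazepam	DIWRORZWFLOCLC-UHFFFAOYSA-N	OC1N=C(c2ccccc2Cl)c2cc(Cl)ccc2NC1=O	Ativan	DB00186	
Haloperidol	LNEPOXFFQSENCJ-UHFFFAOYSA-N	OC1(c2ccc(Cl)cc2)CCN(CCCC(=O)c2ccc(F)cc2)CC1	Haldol	DB00502	
Risperidone	RAPZEAPATHNIPO-UHFFFAOYSA-N	Cc1nc2CCCCn2c(=O)c1CCN1CCC(c2noc3cc(F)ccc23)CC1	Risperdal	DB00734	
Olanzapine	KVWDHTXUZHCGIO-UHFFFAOYSA-N	Cc1cc2c(s1)Nc1ccccc1N=C2N1CCN(C)CC1	Zyprexa	DB00334	
Quetiapine	URKOMYMAXPYINW-UHFFFAOYSA-N	OCCOCCN1CCN(C2=Nc3ccccc3Sc3ccccc32)CC1	Seroquel	DB01224	
Loratadine	JCCNYMKQOSZNPW-UHFFFAOYSA-N	CCOC(=O)N1CCC(=C2c3ccc(Cl)cc3CCc3cccnc32)CC1	Claritin	DB00455	
Cetirizine	ZKLPARSLTMPFCP-UHFFFAOYSA-N	OC(=O)COCCN1CCN(C(c2ccccc2)c2ccc(Cl)cc2)CC1	Zyrtec	DB00341	
Furosemide	ZZUFCTLCJUWOSV-UHFFFAOYSA-N	NS(=O)(=O)c1cc(C(=O)O)c(NCc2ccco2)cc1Cl	Lasix	DB00695	
Hydrochlorothiazide	JZUFKLXOESDKRF-UHFFFAOYSA-N	NS(=O)(=O)c1cc2c(cc1Cl)NCNS2(=O)=O	HCTZ	DB00999	
Amlodipine	HTIQEAQVCYTUBX-UHFFFAOYSA-N	CCOC(=O)C1=C(COCCN)NC(C)=C(C(=O)OC)C1c1ccccc1Cl	Norvasc	DB00381	
Verapamil	SGTNSNPWRIOYBX-UHFFFAOYSA-N	COc1ccc(CCN(C)CCCC(C#N)(C(C)C)c2ccc(OC)c(OC)c2)cc1OC	Calan	DB00661	
Nifedipine	HYIMSNHJOBLJNT-UHFFFAOYSA-N	COC(=O)C1=C(C)NC(C)=C(C(=O)OC)C1c1ccccc1[N+](=O)[O-]	Procardia	DB01115	
Captopril	FAKRSMQSSFJEIM-RITPCOANSA-N	CC(CS)C(=O)N1CCCC1C(=O)O	Capoten	DB01197	
Naproxen	CMWTZPSULFXXJA-VIFPVBQESA-N	COc1ccc2cc(C(C)C(=O)O)ccc2c1	Aleve	DB00788	
Celecoxib	RZEKVGVHFLEQIL-UHFFFAOYSA-N	Cc1ccc(-c2cc(C(F)(F)F)nn2-c2ccc(S(N)(=O)=O)cc2)cc1	Celebrex	DB00482	
Chloroquine	WHTVZRBIWZFKQO-UHFFFAOYSA-N	CCN(CC)CCCC(C)Nc1ccnc2cc(Cl)ccc12	Aralen	DB00608	
Hydroxychloroquine	XXSMGPRMXLTPCZ-UHFFFAOYSA-N	CCN(CCO)CCCC(C)Nc1ccnc2cc(Cl)ccc12	Plaquenil	DB01611	
Metronidazole	VAOCPAMSLUNLGC-UHFFFAOYSA-N	Cc1ncc([N+](=O)[O-])n1CCO	Flagyl	DB00916	
Ondansetron	FELGMEQIXOGIFQ-UHFFFAOYSA-N	Cc1nccn1CC1CCc2c(C1=O)c1ccccc1n2C	Zofran	DB00904	
Tamoxifen	NKANXQFJJICGDU-QPLCGJKRSA-N	CCC(=C(c1ccccc1)c1ccc(OCCN(C)C)cc1)c1ccccc1	Nolvadex	DB00675	
Methotrexate	FBOZXECLQNJBKD-ZDUSSCGKSA-N	CN(Cc1cnc2nc(N)nc(N)c2n1)c1ccc(C(=O)NC(CCC(=O)O)C(=O)O)cc1	MTX	DB00563	
Fluorouracil	GHASVSINZRGABV-UHFFFAOYSA-N	Fc1c[nH]c(=O)[nH]c1=O	5-FU|5-fluorouracil	DB00544	
Ethanol	LFQSCWFLJHTTHZ-UHFFFAOYSA-N	CCO	alcohol|ethyl alcohol	DB00898	
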