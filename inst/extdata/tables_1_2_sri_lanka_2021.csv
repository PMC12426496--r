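table,section,drug_label,drug_name,indication,indication_id,option_group,setting,outcome_measure,gain_value,gain_unit,follow_up_years,age_dx_years,toxicity_grade3plus,esmo_mcbs,course_cost_usd,cost_per_ly_usd,gdp_fraction,n_patients,annual_cost_usd
1,curative,Trastuzumab (6 months),trastuzumab,Adjuvant treatment of non-metastatic breast cancer,trastuzumab_adjuvant_6mo,breast_adjuvant_her2,curative,OS,0.065,proportion,10,47,0.03,A,1502,1156,0.3,880,1322000
1,curative,Trastuzumab (12 months),trastuzumab,Adjuvant treatment of non-metastatic breast cancer,trastuzumab_adjuvant_12mo,breast_adjuvant_her2,curative,OS,0.065,proportion,10,47,0.08,,2951,2270,0.6,880,2597161
1,palliative,Rituximab (maintenance),rituximab,Follicular lymphoma (maintenance),rituximab_follicular_maintenance,follicular_maintenance,palliative,PFS,79,months,,,0.10,not_scored,1550,795,0.06,50,76748
1,palliative,Bortezomib,bortezomib,Multiple myeloma (first line),bortezomib_mm_first_line,mm_first_line,palliative,OS,13.3,months,,,0.30,not_scored,485,437,0.11,475,230216
1,palliative,Abiraterone 250 mg,abiraterone,Metastatic hormone-sensitive prostate cancer,abiraterone_250_hspc,prostate_hspc,palliative,OS,16.8,months,,,0.20,4,945,675,0.18,500,472447
1,palliative,Abiraterone 250 mg,abiraterone,Metastatic castration-resistant prostate cancer (post-docetaxel),abiraterone_250_crpc_post_docetaxel,crpc_post_docetaxel_abiraterone,palliative,OS,3.9,months,,,0.20,4,289,1198,0.23,100,28943
1,palliative,Rituximab (with chemotherapy),rituximab,Non-Hodgkin lymphoma (first line),rituximab_nhl_first_line,nhl_first_line,palliative,OS,13,months,,,0.10,not_scored,1034,530,0.14,750,775235
1,palliative,Gefitinib,gefitinib,Metastatic adenocarcinoma of lung (first line),gefitinib_lung_egfr_first_line,lung_egfr_first_line,palliative,PFS,5.4,months,,,0.30,4,447,994,0.26,340,134240
1,palliative,Abiraterone 250 mg,abiraterone,Metastatic castration-resistant prostate cancer (pre-docetaxel),abiraterone_250_crpc_pre_docetaxel,crpc_pre_docetaxel,palliative,OS,4.4,months,,,0.20,4,502,1370,0.36,300,150672
1,palliative,Erlotinib,erlotinib,Metastatic adenocarcinoma of lung (first line),erlotinib_lung_egfr_first_line,lung_egfr_first_line,palliative,OS,8.5,months,,,0.15,4,1003,2314,0.37,340,340902
1,palliative,Lenalidomide,lenalidomide,Multiple myeloma (transplant-ineligible first line),lenalidomide_mm_ti_first_line,mm_ti_first_line,palliative,OS,13.2,months,,,0.30,not_scored,1704,1550,0.41,475,809629
1,palliative,Trastuzumab,trastuzumab,Metastatic breast cancer,trastuzumab_metastatic_breast,breast_met_her2,palliative,OS,4.8,months,,,0.08,not_assessed,2146,1764,0.46,264,566653
1,palliative,Pomalidomide,pomalidomide,Multiple myeloma (second line),pomalidomide_mm_second_line,mm_second_line,palliative,OS,4.4,months,,,0.15,not_assessed,1055,1809,0.47,333,350879
1,palliative,"Abiraterone 1,000 mg",abiraterone,Metastatic hormone-sensitive prostate cancer,abiraterone_1000_hspc,prostate_hspc,palliative,OS,16.8,months,,,0.20,4,3780,2700,0.71,500,1889789
1,palliative,"Abiraterone 1,000 mg",abiraterone,Metastatic castration-resistant prostate cancer (post-docetaxel),abiraterone_1000_crpc_post_docetaxel,crpc_post_docetaxel_abiraterone,palliative,OS,3.9,months,,,0.20,4,1158,3562,0.93,100,115771
1,palliative,Cabazitaxel,cabazitaxel,Metastatic castration-resistant prostate cancer (post-docetaxel),cabazitaxel_crpc_post_docetaxel,crpc_post_docetaxel_cabazitaxel,palliative,OS,2.6,months,,,0.50,3,774,3573,0.94,100,77423
1,palliative,Fulvestrant 250 mg,fulvestrant,Metastatic breast cancer (first line) with anastrozole,fulvestrant_250_mbc_first_line,breast_met_endocrine_first_line,palliative,OS,7.8,months,,,0.20,not_assessed,2433,3743,0.98,330,802938
2,curative,Osimertinib,osimertinib,Adjuvant treatment of resected stage IIB-III EGFR-mutant adenocarcinoma of lung,osimertinib_adjuvant_lung,lung_egfr_adjuvant,curative,DFS,0.50,proportion,3,64.5,,A,29692,6252,1.64,55,1633036
2,curative,Goserelin,goserelin,Adjuvant treatment of localised prostate cancer with radical radiotherapy,goserelin_adjuvant_prostate,prostate_localised_rt,curative,DSS,0.048,proportion,10,62,,not_scored,1536,6399,1.68,300,460764
2,curative,Olaparib,olaparib,Adjuvant treatment of germline BRCA-mutant early breast cancer,olaparib_adjuvant_breast,breast_brca_adjuvant,curative,DFS,0.088,proportion,3,42.5,,A,21746,7845,2.06,110,2392052
2,palliative,Topotecan,topotecan,Metastatic cervical cancer (second line),topotecan_cervix_second_line,cervix_second_line,palliative,OS,2.9,months,,,,not_scored,1015,4201,1.1,110,111672
2,palliative,Sunitinib,sunitinib,Metastatic renal cell carcinoma,sunitinib_mrcc_first_line,rcc_first_line,palliative,OS,14,months,,,,4,5619,4816,1.26,100,561900
2,palliative,Sunitinib,sunitinib,Advanced gastrointestinal stromal tumour (second line),sunitinib_gist_second_line,gist_second_line,palliative,OS,20.9,months,,,,3,504992,5268,1.38,10,35120
2,palliative,Trastuzumab,trastuzumab,Metastatic adenocarcinoma of stomach,trastuzumab_gastric,gastric_her2,palliative,OS,2.7,months,,,,3,1222,5433,1.42,65,79454
2,palliative,"Abiraterone 1,000 mg",abiraterone,Metastatic castration-resistant prostate cancer (pre-docetaxel),abiraterone_1000_crpc_pre_docetaxel,crpc_pre_docetaxel,palliative,OS,4.4,months,,,,4,289,5479,1.44,300,602689
2,palliative,Fulvestrant 500 mg,fulvestrant,Metastatic breast cancer (second line),fulvestrant_500_mbc_second_line,breast_met_endocrine_second_line,palliative,OS,4.1,months,,,,not_assessed,502,5997,1.57,440,901545
2,palliative,Pazopanib,pazopanib,Metastatic renal cell carcinoma,pazopanib_mrcc_first_line,rcc_first_line,palliative,OS,14,months,,,,4,7780,6669,1.75,100,778000
2,palliative,Bevacizumab,bevacizumab,Platinum-refractory advanced epithelial ovarian cancer,bevacizumab_ovarian_plat_refractory,ovary_platinum_refractory,palliative,OS,3.3,months,,,,4,2046,7442,1.95,285,583247
2,palliative,Everolimus,everolimus,Advanced renal cell carcinoma (second line),everolimus_rcc_second_line,rcc_second_line,palliative,OS,3,months,,,,3,1003,8814,2.31,40,88143
2,palliative,Nab-paclitaxel,nab_paclitaxel,Unresectable pancreatic cancer,nab_paclitaxel_pancreas,pancreas_unresectable,palliative,OS,2.4,months,,,,2,2180,10063,2.64,135,294337
2,palliative,Pazopanib,pazopanib,Metastatic soft-tissue sarcoma (second line),pazopanib_sts_second_line,sts_second_line,palliative,OS,3,months,,,,3,2640,10559,2.77,26,68634
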