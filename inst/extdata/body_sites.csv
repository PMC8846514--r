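body_site,human_taxid,generic_taxid
Gut,408170,749906
Human metagenome,646099,NA
Oral,447426,1499682
Skin,539655,256318
Vaginal,1632839,1549827
Lung,433733,1480792
Nasopharyngeal,1131769,2509717
Feces,1118061,NA
Reproductive system,1842734,NA
Blood,1504969,655179
Saliva,1679718,NA
Milk,1633571,1430582
Urinary tract,1852362,NA
Tracheal,1712573,NA
Sputum,2066807,NA
Eye,1774142,NA
Semen,1837932,NA
Bile,1630596,NA
Skeleton,2653827,NA
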