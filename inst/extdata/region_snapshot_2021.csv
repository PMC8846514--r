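group,unit,samples,population_thousands
region,Europe and Northern America,272544,1116506
region,Eastern and Southeastern Asia,49007,2346709
region,Sub-Saharan Africa,18651,1094366
region,Latin America and the Caribbean,15264,653962
region,Australia/New Zealand,13620,30322
region,Central and Southern Asia,6685,2014709
region,Northern Africa and Western Asia,5621,525869
region,Oceania,1178,12356
region_unknown,Unknown,62259,NA
ldc,Least developed countries,15254,1057438
ldc,Rest of world,367457,6737361
ldc_unknown,Unknown,62118,NA
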