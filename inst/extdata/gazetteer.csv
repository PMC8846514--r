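alias,country_code
United States of America,USA
USA,USA
US,USA
U.S.A.,USA
United States,USA
UK,GBR
United Kingdom of Great Britain and Northern Ireland,GBR
Great Britain,GBR
England,GBR
Scotland,GBR
Wales,GBR
Northern Ireland,GBR
the Netherlands,NLD
The Netherlands,NLD
Holland,NLD
Russian Federation,RUS
Viet Nam,VNM
Republic of Korea,KOR
Korea Republic of,KOR
South Korea,KOR
Democratic People's Republic of Korea,PRK
Czech Republic,CZE
Republic of Moldova,MDA
Macedonia,MKD
Bolivia (Plurinational State of),BOL
Venezuela (Bolivarian Republic of),VEN
Iran (Islamic Republic of),IRN
Syrian Arab Republic,SYR
Lao People's Democratic Republic,LAO
Brunei Darussalam,BRN
Myanmar (Burma),MMR
Burma,MMR
United Republic of Tanzania,TZA
Cote d'Ivoire,CIV
Côte d'Ivoire,CIV
Democratic Republic of Congo,COD
DR Congo,COD
DRC,COD
Congo Democratic Republic,COD
Congo,COG
Cape Verde,CPV
Swaziland,SWZ
Sao Tome & Principe,STP
Türkiye,TUR
Turkiye,TUR
State of Palestine,PSE
Hong Kong SAR China,HKG
Hong Kong China,HKG
China: Hong Kong,HKG
Macau,MAC
Taiwan Province of China,TWN
Republic of China,TWN
East Timor,TLS
Federated States of Micronesia,FSM
New Zealand (Aotearoa),NZL
Aotearoa,NZL
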