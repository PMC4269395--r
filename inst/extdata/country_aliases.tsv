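alias	canonical
Korea, Republic of	South Korea
Republic of Korea	South Korea
Korea, Democratic People's Republic of	North Korea
Russian Federation	Russia
Iran, Islamic Republic of	Iran
Syrian Arab Republic	Syria
Viet Nam	Vietnam
Taiwan, Province of China	Taiwan
Congo, The Democratic Republic of the	Democratic Republic of the Congo
Congo, Democratic Republic of the	Democratic Republic of the Congo
Lao People's Democratic Republic	Laos
Libyan Arab Jamahiriya	Libya
Macedonia, The Former Yugoslav Republic of	North Macedonia
Former Yugoslav Republic of Macedonia	North Macedonia
Macedonia	North Macedonia
Moldova, Republic of	Moldova
Tanzania, United Republic of	Tanzania
Venezuela, Bolivarian Republic of	Venezuela
Bolivia, Plurinational State of	Bolivia
Micronesia, Federated States of	Micronesia
Brunei Darussalam	Brunei
Cote d'Ivoire	Ivory Coast
Côte d'Ivoire	Ivory Coast
Czechia	Czech Republic
Holy See (Vatican City State)	Vatican City
Holy See	Vatican City
Swaziland	Eswatini
Burma	Myanmar
Cabo Verde	Cape Verde
East Timor	Timor-Leste
Palestinian Territory, occupied	Palestinian Territories
Occupied Palestinian Territories	Palestinian Territories
Palestine	Palestinian Territories
United States of America	United States
USA	United States
U.S.A.	United States
US	United States
United Kingdom of Great Britain and Northern Ireland	United Kingdom
Great Britain	United Kingdom
UK	United Kingdom
U.K.	United Kingdom
Hong Kong SAR, China	Hong Kong
Macao	Macau
The Netherlands	Netherlands
Netherlands, The	Netherlands
Gambia, The	Gambia
Bahamas, The	Bahamas
Federated States of Micronesia	Micronesia
Republic of the Congo	Congo
Kampuchea	Cambodia
Ceylon	Sri Lanka
Turkiye	Turkey
Türkiye	Turkey
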