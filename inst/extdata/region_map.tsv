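country	region
Afghanistan	Asia
Albania	Europe
Algeria	Africa
American Samoa	Oceania
Andorra	Europe
Angola	Africa
Antigua and Barbuda	North America
Argentina	South America
Armenia	Asia
Australia	Oceania
Austria	Europe
Azerbaijan	Asia
Bahamas	North America
Bahrain	Asia
Bangladesh	Asia
Barbados	North America
Belarus	Europe
Belgium	Europe
Belize	North America
Benin	Africa
Bermuda	North America
Bhutan	Asia
Bolivia	South America
Bosnia and Herzegovina	Europe
Botswana	Africa
Brazil	South America
Brunei	Asia
Bulgaria	Europe
Burkina Faso	Africa
Burundi	Africa
Cambodia	Asia
Cameroon	Africa
Canada	North America
Cape Verde	Africa
Central African Republic	Africa
Chad	Africa
Chile	South America
China	Asia
Colombia	South America
Comoros	Africa
Congo	Africa
Costa Rica	North America
Croatia	Europe
Cuba	North America
Cyprus	Europe
Czech Republic	Europe
Democratic Republic of the Congo	Africa
Denmark	Europe
Djibouti	Africa
Dominica	North America
Dominican Republic	North America
Ecuador	South America
Egypt	Africa
El Salvador	North America
Equatorial Guinea	Africa
Eritrea	Africa
Estonia	Europe
Eswatini	Africa
Ethiopia	Africa
Fiji	Oceania
Finland	Europe
France	Europe
French Guiana	South America
French Polynesia	Oceania
Gabon	Africa
Gambia	Africa
Georgia	Asia
Germany	Europe
Ghana	Africa
Gibraltar	Europe
Greece	Europe
Greenland	North America
Grenada	North America
Guam	Oceania
Guatemala	North America
Guinea	Africa
Guinea-Bissau	Africa
Guyana	South America
Haiti	North America
Honduras	North America
Hong Kong	Asia
Hungary	Europe
Iceland	Europe
India	Asia
Indonesia	Asia
Iran	Asia
Iraq	Asia
Ireland	Europe
Israel	Asia
Italy	Europe
Ivory Coast	Africa
Jamaica	North America
Japan	Asia
Jordan	Asia
Kazakhstan	Asia
Kenya	Africa
Kiribati	Oceania
Kosovo	Europe
Kuwait	Asia
Kyrgyzstan	Asia
Laos	Asia
Latvia	Europe
Lebanon	Asia
Lesotho	Africa
Liberia	Africa
Libya	Africa
Liechtenstein	Europe
Lithuania	Europe
Luxembourg	Europe
Macau	Asia
Madagascar	Africa
Malawi	Africa
Malaysia	Asia
Maldives	Asia
Mali	Africa
Malta	Europe
Marshall Islands	Oceania
Mauritania	Africa
Mauritius	Africa
Mexico	North America
Micronesia	Oceania
Moldova	Europe
Monaco	Europe
Mongolia	Asia
Montenegro	Europe
Morocco	Africa
Mozambique	Africa
Myanmar	Asia
Namibia	Africa
Nauru	Oceania
Nepal	Asia
Netherlands	Europe
New Caledonia	Oceania
New Zealand	Oceania
Nicaragua	North America
Niger	Africa
Nigeria	Africa
North Korea	Asia
North Macedonia	Europe
Norway	Europe
Oman	Asia
Pakistan	Asia
Palau	Oceania
Palestinian Territories	Asia
Panama	North America
Papua New Guinea	Oceania
Paraguay	South America
Peru	South America
Philippines	Asia
Poland	Europe
Portugal	Europe
Puerto Rico	North America
Qatar	Asia
Romania	Europe
Russia	Europe
Rwanda	Africa
Saint Kitts and Nevis	North America
Saint Lucia	North America
Saint Vincent and the Grenadines	North America
Samoa	Oceania
San Marino	Europe
Sao Tome and Principe	Africa
Saudi Arabia	Asia
Senegal	Africa
Serbia	Europe
Seychelles	Africa
Sierra Leone	Africa
Singapore	Asia
Slovakia	Europe
Slovenia	Europe
Solomon Islands	Oceania
Somalia	Africa
South Africa	Africa
South Korea	Asia
South Sudan	Africa
Spain	Europe
Sri Lanka	Asia
Sudan	Africa
Suriname	South America
Sweden	Europe
Switzerland	Europe
Syria	Asia
Taiwan	Asia
Tajikistan	Asia
Tanzania	Africa
Thailand	Asia
Timor-Leste	Asia
Togo	Africa
Tonga	Oceania
Trinidad and Tobago	North America
Tunisia	Africa
Turkey	Asia
Turkmenistan	Asia
Tuvalu	Oceania
Uganda	Africa
Ukraine	Europe
United Arab Emirates	Asia
United Kingdom	Europe
United States	North America
Uruguay	South America
Uzbekistan	Asia
Vanuatu	Oceania
Vatican City	Europe
Venezuela	South America
Vietnam	Asia
Yemen	Asia
Zambia	Africa
Zimbabwe	Africa
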