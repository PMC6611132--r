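country,region
United States,Northern America
Canada,Northern America
United Kingdom,Western Europe
Netherlands,Western Europe
Germany,Western Europe
France,Western Europe
Italy,Western Europe
Spain,Western Europe
Denmark,Western Europe
Sweden,Western Europe
Norway,Western Europe
Switzerland,Western Europe
Austria,Western Europe
Belgium,Western Europe
Finland,Western Europe
Ireland,Western Europe
Portugal,Western Europe
Greece,Western Europe
Iceland,Western Europe
China,Asia (excluding Near East)
Japan,Asia (excluding Near East)
South Korea,Asia (excluding Near East)
India,Asia (excluding Near East)
Taiwan,Asia (excluding Near East)
Singapore,Asia (excluding Near East)
Thailand,Asia (excluding Near East)
Malaysia,Asia (excluding Near East)
Indonesia,Asia (excluding Near East)
Vietnam,Asia (excluding Near East)
Pakistan,Asia (excluding Near East)
Bangladesh,Asia (excluding Near East)
Australia,Oceania
New Zealand,Oceania
Brazil,Latin America and Caribbean
Mexico,Latin America and Caribbean
Argentina,Latin America and Caribbean
Chile,Latin America and Caribbean
Colombia,Latin America and Caribbean
Peru,Latin America and Caribbean
Cuba,Latin America and Caribbean
Israel,Near East
Turkey,Near East
Saudi Arabia,Near East
Iran,Near East
United Arab Emirates,Near East
Jordan,Near East
Lebanon,Near East
Qatar,Near East
South Africa,Sub-Saharan Africa
Nigeria,Sub-Saharan Africa
Kenya,Sub-Saharan Africa
Ghana,Sub-Saharan Africa
Ethiopia,Sub-Saharan Africa
Uganda,Sub-Saharan Africa
Poland,Eastern Europe
Czechia,Eastern Europe
Hungary,Eastern Europe
Romania,Eastern Europe
Croatia,Eastern Europe
Serbia,Eastern Europe
Slovakia,Eastern Europe
Slovenia,Eastern Europe
Bulgaria,Eastern Europe
Egypt,Northern Africa
Morocco,Northern Africa
Tunisia,Northern Africa
Algeria,Northern Africa
Estonia,Baltics
Latvia,Baltics
Lithuania,Baltics
Russia,Commonwealth of Independent States
Ukraine,Commonwealth of Independent States
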