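code,name,population_2012,income_group,region,continent
US,United States,313914040,high,North America,North America
CA,Canada,34754312,high,North America,North America
MX,Mexico,117053750,upper_middle,North America,North America
BR,Brazil,198656019,upper_middle,South America,South America
AR,Argentina,41086927,upper_middle,South America,South America
CL,Chile,17464814,upper_middle,South America,South America
CO,Colombia,47704427,upper_middle,South America,South America
DE,Germany,80425823,high,Western Europe,Europe
FR,France,65676758,high,Western Europe,Europe
GB,United Kingdom,63700300,high,Western Europe,Europe
IT,Italy,59539717,high,Western Europe,Europe
ES,Spain,46773055,high,Western Europe,Europe
NL,Netherlands,16754962,high,Western Europe,Europe
CH,Switzerland,7996861,high,Western Europe,Europe
SE,Sweden,9519374,high,Western Europe,Europe
DK,Denmark,5591572,high,Western Europe,Europe
NO,Norway,5018573,high,Western Europe,Europe
PL,Poland,38535873,high,Eastern Europe,Europe
CZ,Czech Republic,10510785,high,Eastern Europe,Europe
HU,Hungary,9920362,upper_middle,Eastern Europe,Europe
RO,Romania,20076727,upper_middle,Eastern Europe,Europe
BG,Bulgaria,7305888,upper_middle,Eastern Europe,Europe
RU,Russia,143201676,upper_middle,Eastern Europe,Europe
UA,Ukraine,45593342,lower_middle,Eastern Europe,Europe
RS,Serbia,7199077,upper_middle,Eastern Europe,Europe
TR,Turkey,74099255,upper_middle,Asia,Asia
CN,China,1350695000,upper_middle,Asia,Asia
IN,India,1236686732,lower_middle,Asia,Asia
JP,Japan,127561489,high,Asia,Asia
KR,South Korea,50004441,high,Asia,Asia
TH,Thailand,67164130,upper_middle,Asia,Asia
IL,Israel,7910500,high,Asia,Asia
ZA,South Africa,52274945,upper_middle,Africa,Africa
EG,Egypt,85660902,lower_middle,Africa,Africa
NG,Nigeria,168240403,lower_middle,Africa,Africa
KE,Kenya,43178141,low,Africa,Africa
ET,Ethiopia,92191211,low,Africa,Africa
TZ,Tanzania,47783107,low,Africa,Africa
AU,Australia,22728254,high,Oceania,Oceania
NZ,New Zealand,4433100,high,Oceania,Oceania
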