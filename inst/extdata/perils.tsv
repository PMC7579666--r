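# Generic taxonomy of 19 peril classes (row order fixes matrix index order).
# Columns: id (two-letter code), name, origin, system.
id	name	origin	system
EQ	Earthquake	geological/geomorphological	natural
VE	Volcanic eruption	geological/geomorphological	natural
MS	Mass slide	geological/geomorphological	natural
FL	Flood	hydrological	natural
WS	Windstorm	meteorological	natural
OS	Other storm	meteorological	natural
EW	Extreme weather	meteorological	natural
WF	Wildfire	biophysical/ecological	natural
DI	Disease	biophysical/ecological	natural
AI	Asteroid impact	extraterrestrial	natural
GS	Geomagnetic storm	extraterrestrial	natural
FI	Fire	technological	anthropogenic
CF	Critical infrastructure failure	technological	anthropogenic
NF	Critical network failure	technological	anthropogenic
BI	Business interruption	economical	anthropogenic
EC	Economic crisis	economical	anthropogenic
SU	Social unrest	social	anthropogenic
HD	Healthcare degradation	social	anthropogenic
CO	Conflict	social	anthropogenic
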