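year,quota,advice
2007,90,
2008,80,
2009,75,
2010,64,68
2011,64,68
2012,64,68
2013,74,89
2014,86,89
2015,86,89
2016,86,85
2017,85,
2018,85,
2019,85,
2020,85,
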