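"year","amount_hkd"
2009,5.2e+07
2010,7e+07
2011,9e+07
2012,2.2e+08
2013,5.1e+08
2014,1.1e+09
2015,1.3e+09
2016,1.4e+09
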