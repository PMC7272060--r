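period_id,n_marked
Dec 2013,2000
Dec 2014,1930
Feb 2016,482
Nov 2016,781
Dec 2016,2000
Dec 2017,2000
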