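scenario_id,source,expected_low_percent,expected_high_percent,note
2,ESIG,80,90,partial enclosure with extraction: professional 80 / industrial 90
3,ESIG,90,95,extracted full enclosure: professional 90 / industrial 95
4,TRA,75,95,LEV general 75-95; PROCs 8a/8b/9 80-95; general ventilation 30/70
5,ESIG,80,80,drum pump: all uses 80
6,ESIG,80,80,drum pump under containment/extraction: all uses 80
7,TRA,75,95,LEV general 75-95; PROCs 8a/8b/9 80-95; general ventilation 30/70
9,ESIG,90,90,drain and flush: industrial 90
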