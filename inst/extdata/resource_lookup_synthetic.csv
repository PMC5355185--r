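code,name,coverage_p1,coverage_p2,attract_p1,attract_p2,nesting_quality,is_agricultural
1,oilseed_rape,0.9,0,600,0,0.05,TRUE
2,cereal,0.02,0.01,100,100,0.05,TRUE
3,ley,0.4,0.15,1000,133,0.3,TRUE
4,seminatural,0.6,0.3,1000,620,1,FALSE
5,non_habitat,0,0,0,0,0,FALSE
6,flower_strip,0,0.9,0,1000,0.05,FALSE
7,field_margin,0.04,0.05,60,60,1,FALSE
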