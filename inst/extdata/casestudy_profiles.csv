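profile,n,pct,criterion.excellent,criterion.enhanced,criterion.acceptable,criterion.not_classified,principle.excellent,principle.enhanced,principle.acceptable,principle.not_classified,overall.excellent,overall.enhanced,overall.acceptable,overall.not_classified
Profile 1,2,4.5,0,100,0,0,0,100.0,0,0,0,50,50,0
Profile 2,6,13.6,0,50.0,50.0,0,0,50.0,50.0,0,0,66.7,33.3,0
Profile 3,14,31.8,0,7.1,92.9,0,0,0,100.0,0,0,42.9,57.1,0
Profile 4,4,9.1,0,0,50.0,50.0,0,0,100.0,0,0,25,75,0
Profile 5,2,4.5,0,0,100.0,0,0,0,100.0,0,0,50,50,0
Profile 6,7,15.9,0,14.3,85.7,0,0,14.3,85.7,0,0,71.4,28.6,0
Profile 7,2,4.5,0,0,50.0,0,0,0,100.0,0,0,50,0,50
Profile 8,4,9.1,0,0,75.0,25.0,0,0,100.0,0,0,75,25,0
Profile 9,3,6.8,0,0,66.7,33.3,0,0,100.0,0,0,0,100,0
Total,44,100,0,15.9,72.7,11.4,0,13.6,86.4,0,0,50,47.7,2.3
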