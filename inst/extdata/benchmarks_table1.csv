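source,stratum,rate_per_100k
CAC,general,10.5
NCI,general,9.8
GLOBOCAN,general,15.7
CAC,sex=male,10.1
NCI,sex=male,12
GLOBOCAN,sex=male,16.9
CAC,sex=female,10.9
NCI,sex=female,7.5
GLOBOCAN,sex=female,14.5
CAC,age_group=20-44,0.9
GLOBOCAN,age_group=20-44,1.1
CAC,age_group=45-64,11.1
GLOBOCAN,age_group=45-64,17.4
CAC,age_group=65+,49.2
GLOBOCAN,age_group=65+,82.7
NCI,region=Atlantic,7.2
NCI,region=Bogota,7.1
NCI,region=Central,16
NCI,region=Oriental,8.2
NCI,region=Orinoquia/Amazonia,4
NCI,region=Pacific,9.4
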