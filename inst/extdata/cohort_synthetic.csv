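id,age_dx,sex,year_dx,stage,her2,er,pr,adherence_rate,followup_years,dead
sim000001,67.9,female,2008,II,neg,pos,pos,0.906,6.741,1
sim000002,50.1,female,2008,I,pos,pos,pos,0.93,12.175,0
sim000003,64.6,female,2009,III,neg,pos,pos,0.951,10.369,0
sim000004,50.5,female,2007,III,pos,pos,pos,0.949,12.853,0
sim000005,64.9,female,2007,III,pos,pos,pos,0.911,12.556,0
sim000006,47.6,female,2008,I,pos,pos,pos,0.893,12.369,0
sim000007,65.9,female,2007,I,neg,pos,pos,0.501,11.555,0
sim000008,59.7,female,2008,I,neg,pos,pos,0.855,10.4,0
sim000009,32.9,female,2009,I,neg,pos,pos,0.971,12.482,0
sim000010,60.5,female,2009,II,pos,pos,pos,0.895,12.019,0
sim000011,61.8,female,2007,II,neg,pos,pos,0.845,11.064,0
sim000012,72,female,2007,II,neg,pos,pos,0.254,9.11,1
sim000013,68.8,female,2008,I,neg,pos,pos,0.858,11.63,0
sim000014,77.9,female,2007,I,neg,pos,pos,0.81,10.279,0
sim000015,74.4,female,2009,II,neg,pos,pos,0.95,12.851,0
sim000016,53.9,female,2009,II,pos,pos,pos,0.995,12.522,0
sim000017,39.5,female,2007,III,neg,pos,pos,0.918,10.966,0
sim000018,69,female,2007,III,neg,pos,pos,0.848,0.141,1
sim000019,70.5,female,2009,II,pos,pos,pos,0.947,12.747,0
sim000020,62.6,female,2007,II,neg,pos,pos,0.079,12.698,0
sim000021,72.1,female,2008,II,pos,pos,pos,0.841,7.118,1
sim000022,79.6,female,2007,I,neg,pos,pos,0.875,12.735,0
sim000023,54.3,female,2008,I,neg,pos,pos,0.721,10.892,0
sim000024,52.4,female,2009,III,neg,pos,pos,0.945,11.217,0
sim000025,73.1,female,2007,I,neg,pos,pos,0.964,6.478,1
sim000026,67.5,female,2007,II,neg,pos,pos,0.909,10.437,1
sim000027,73.6,female,2007,II,neg,pos,pos,0.874,10.248,0
sim000028,77.6,female,2009,I,pos,pos,pos,0.819,9.516,1
sim000029,62.2,female,2009,I,neg,pos,pos,0.87,10.713,0
sim000030,70.4,female,2007,I,pos,pos,pos,0.987,12.205,0
sim000031,50.9,female,2009,I,pos,pos,pos,0.942,12.83,0
sim000032,32.2,female,2007,I,neg,pos,pos,0.13,10.486,0
sim000033,48.7,female,2009,I,neg,pos,pos,0.934,10.074,0
sim000034,75.6,female,2008,I,neg,pos,pos,0.983,9.481,1
sim000035,55.2,female,2007,I,pos,pos,pos,0.812,11.117,0
sim000036,59.6,female,2009,I,neg,pos,pos,0.954,10.771,0
sim000037,68.5,female,2007,III,neg,pos,pos,0.926,9.489,1
sim000038,59.7,female,2008,II,neg,pos,pos,0.932,11.946,1
sim000039,58.2,female,2008,II,neg,pos,pos,0.914,11.096,0
sim000040,63.1,female,2008,I,neg,pos,pos,0.908,12.66,0
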