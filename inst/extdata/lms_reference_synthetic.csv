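sex,agemos,L,M,S
female,144,-2,19.4,0.14
female,148,-1.9833,19.5167,0.1392
female,152,-1.9667,19.6333,0.1383
female,156,-1.95,19.75,0.1375
female,160,-1.9333,19.8667,0.1367
female,164,-1.9167,19.9833,0.1358
female,168,-1.9,20.1,0.135
female,172,-1.8833,20.2167,0.1342
female,176,-1.8667,20.3333,0.1333
female,180,-1.85,20.45,0.1325
female,184,-1.8333,20.5667,0.1317
female,188,-1.8167,20.6833,0.1308
female,192,-1.8,20.8,0.13
female,196,-1.7833,20.9167,0.1292
female,200,-1.7667,21.0333,0.1283
female,204,-1.75,21.15,0.1275
female,208,-1.7333,21.2667,0.1267
female,212,-1.7167,21.3833,0.1258
female,216,-1.7,21.5,0.125
female,220,-1.6833,21.6167,0.1242
female,224,-1.6667,21.7333,0.1233
female,228,-1.65,21.85,0.1225
female,232,-1.6333,21.9667,0.1217
female,236,-1.6167,22.0833,0.1208
female,240,-1.6,22.2,0.12
male,144,-2.2,19,0.135
male,148,-2.1792,19.1583,0.1344
male,152,-2.1583,19.3167,0.1338
male,156,-2.1375,19.475,0.1331
male,160,-2.1167,19.6333,0.1325
male,164,-2.0958,19.7917,0.1319
male,168,-2.075,19.95,0.1312
male,172,-2.0542,20.1083,0.1306
male,176,-2.0333,20.2667,0.13
male,180,-2.0125,20.425,0.1294
male,184,-1.9917,20.5833,0.1288
male,188,-1.9708,20.7417,0.1281
male,192,-1.95,20.9,0.1275
male,196,-1.9292,21.0583,0.1269
male,200,-1.9083,21.2167,0.1262
male,204,-1.8875,21.375,0.1256
male,208,-1.8667,21.5333,0.125
male,212,-1.8458,21.6917,0.1244
male,216,-1.825,21.85,0.1238
male,220,-1.8042,22.0083,0.1231
male,224,-1.7833,22.1667,0.1225
male,228,-1.7625,22.325,0.1219
male,232,-1.7417,22.4833,0.1213
male,236,-1.7208,22.6417,0.1206
male,240,-1.7,22.8,0.12
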