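"vessel_id","s_mm","vffr"
"EX001",0,1
"EX001",0.2,0.998987
"EX001",0.4,0.997975
"EX001",0.6,0.996962
"EX001",0.8,0.995949
"EX001",1,0.994937
"EX001",1.2,0.993924
"EX001",1.4,0.992911
"EX001",1.6,0.991899
"EX001",1.8,0.990886
"EX001",2,0.989873
"EX001",2.2,0.988861
"EX001",2.4,0.987848
"EX001",2.6,0.986835
"EX001",2.8,0.985823
"EX001",3,0.98481
"EX001",3.2,0.983797
"EX001",3.4,0.982785
"EX001",3.6,0.981772
"EX001",3.8,0.980759
"EX001",4,0.979747
"EX001",4.2,0.978734
"EX001",4.4,0.977722
"EX001",4.6,0.976709
"EX001",4.8,0.975696
"EX001",5,0.974684
"EX001",5.2,0.973671
"EX001",5.4,0.972658
"EX001",5.6,0.971646
"EX001",5.8,0.970633
"EX001",6,0.96962
"EX001",6.2,0.968608
"EX001",6.4,0.967595
"EX001",6.6,0.966582
"EX001",6.8,0.96557
"EX001",7,0.964557
"EX001",7.2,0.963544
"EX001",7.4,0.962532
"EX001",7.6,0.961519
"EX001",7.8,0.960506
"EX001",8,0.960238
"EX001",8.2,0.959958
"EX001",8.4,0.95966
"EX001",8.6,0.959344
"EX001",8.8,0.959007
"EX001",9,0.958647
"EX001",9.2,0.958263
"EX001",9.4,0.957853
"EX001",9.6,0.957413
"EX001",9.8,0.956942
"EX001",10,0.956437
"EX001",10.2,0.955894
"EX001",10.4,0.955312
"EX001",10.6,0.954687
"EX001",10.8,0.954016
"EX001",11,0.953297
"EX001",11.2,0.952527
"EX001",11.4,0.951703
"EX001",11.6,0.950823
"EX001",11.8,0.949886
"EX001",12,0.94889
"EX001",12.2,0.947834
"EX001",12.4,0.94672
"EX001",12.6,0.945547
"EX001",12.8,0.944318
"EX001",13,0.943034
"EX001",13.2,0.941701
"EX001",13.4,0.940323
"EX001",13.6,0.938906
"EX001",13.8,0.937456
"EX001",14,0.93598
"EX001",14.2,0.934488
"EX001",14.4,0.932986
"EX001",14.6,0.931484
"EX001",14.8,0.929986
"EX001",15,0.928495
"EX001",15.2,0.927017
"EX001",15.4,0.925554
"EX001",15.6,0.924111
"EX001",15.8,0.92269
"EX001",16,0.921294
"EX001",16.2,0.919927
"EX001",16.4,0.91859
"EX001",16.6,0.917285
"EX001",16.8,0.916014
"EX001",17,0.914779
"EX001",17.2,0.91358
"EX001",17.4,0.912418
"EX001",17.6,0.911293
"EX001",17.8,0.910205
"EX001",18,0.909154
"EX001",18.2,0.90814
"EX001",18.4,0.907162
"EX001",18.6,0.906219
"EX001",18.8,0.90531
"EX001",19,0.904435
"EX001",19.2,0.903592
"EX001",19.4,0.90278
"EX001",19.6,0.901999
"EX001",19.8,0.901246
"EX001",20,0.900522
"EX001",20.2,0.899825
"EX001",20.4,0.899154
"EX001",20.6,0.898508
"EX001",20.8,0.897886
"EX001",21,0.897287
"EX001",21.2,0.89671
"EX001",21.4,0.896155
"EX001",21.6,0.89562
"EX001",21.8,0.895105
"EX001",22,0.894609
"EX001",22.2,0.89413
"EX001",22.4,0.893669
"EX001",22.6,0.893225
"EX001",22.8,0.892796
"EX001",23,0.892382
"EX001",23.2,0.891983
"EX001",23.4,0.891596
"EX001",23.6,0.891222
"EX001",23.8,0.89086
"EX001",24,0.890506
"EX001",24.2,0.889494
"EX001",24.4,0.888481
"EX001",24.6,0.887468
"EX001",24.8,0.886456
"EX001",25,0.885443
"EX001",25.2,0.88443
"EX001",25.4,0.883418
"EX001",25.6,0.882405
"EX001",25.8,0.881392
"EX001",26,0.88038
"EX001",26.2,0.879367
"EX001",26.4,0.878354
"EX001",26.6,0.877342
"EX001",26.8,0.876329
"EX001",27,0.875316
"EX001",27.2,0.874304
"EX001",27.4,0.873291
"EX001",27.6,0.872278
"EX001",27.8,0.871266
"EX001",28,0.870253
"EX001",28.2,0.869241
"EX001",28.4,0.868228
"EX001",28.6,0.867215
"EX001",28.8,0.866203
"EX001",29,0.86519
"EX001",29.2,0.864177
"EX001",29.4,0.863165
"EX001",29.6,0.862152
"EX001",29.8,0.861139
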