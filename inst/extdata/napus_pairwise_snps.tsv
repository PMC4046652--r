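acc1	acc2	snps
73290	Zhongshuang11	319796
08-806-2	Zhongshuang11	156255
08-806-2	73290	160437
09CB01	Zhongshuang11	249524
09CB01	73290	269446
09CB01	08-806-2	97961
Tapidor	Zhongshuang11	344744
Tapidor	73290	270812
Tapidor	08-806-2	124744
Tapidor	09CB01	177156
XY15	Zhongshuang11	258030
XY15	73290	282982
XY15	08-806-2	104584
XY15	09CB01	30950
XY15	Tapidor	180195
09CB03	Zhongshuang11	382962
09CB03	73290	331329
09CB03	08-806-2	147992
09CB03	09CB01	226364
09CB03	Tapidor	206498
09CB03	XY15	238157
PY-2	Zhongshuang11	171536
PY-2	73290	201921
PY-2	08-806-2	84905
PY-2	09CB01	112203
PY-2	Tapidor	164533
PY-2	XY15	120094
PY-2	09CB03	196957
Westar	Zhongshuang11	326039
Westar	73290	298382
Westar	08-806-2	81868
Westar	09CB01	192659
Westar	Tapidor	198336
Westar	XY15	206164
Westar	09CB03	250136
Westar	PY-2	180579
PY-1	Zhongshuang11	281047
PY-1	73290	385432
PY-1	08-806-2	126870
PY-1	09CB01	170614
PY-1	Tapidor	266468
PY-1	XY15	171196
PY-1	09CB03	324297
PY-1	PY-2	106790
PY-1	Westar	293281
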