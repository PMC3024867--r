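signature_id	label	subunit	family
PF03610	PTS_IIA	IIA	FRU_MAN_SOR
PF03830	PTS_IIB	IIB	FRU_MAN_SOR
PF03609	PTS_IIC	IIC	FRU_MAN_SOR
PF03613	PTS_IID	IID	FRU_MAN_SOR
PF00359	PTS_IIA	IIA	FRU_MANNITOL
PF02302	PTS_IIB	IIB	FRU_MANNITOL
PF02378	PTS_IIC	IIC	FRU_MANNITOL
PF00358	PTS_IIA	IIA	GLUCOSE
PF00367	PTS_IIB	IIB	GLUCOSE
PF02379	PTS_IIC	IIC	GLUCOSE
PF02255	PTS_IIA	IIA	LACTOSE
PF02256	PTS_IIB	IIB	LACTOSE
PF02380	PTS_IIC	IIC	LACTOSE
PF03612	PTS_IIA	IIA	GLUCITOL
PF03608	PTS_IIB	IIB	GLUCITOL
PF03611	PTS_IIC	IIC	GLUCITOL
PF03828	PTS_IIA	IIA	GALACTITOL
PF03829	PTS_IIB	IIB	GALACTITOL
PF03821	PTS_IIC	IIC	GALACTITOL
PF08358	PTS_IIA	IIA	ASCORBATE
PF08359	PTS_IIB	IIB	ASCORBATE
PF08360	PTS_IIC	IIC	ASCORBATE
PF00309	SIGMA54
PF04552	SIGMA54
PF01380	SIS
PF01527	TRANSPOSASE
PF00872	TRANSPOSASE
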