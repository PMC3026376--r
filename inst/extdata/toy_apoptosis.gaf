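!gaf-version: 2.2
!generated for the toy apoptosis ontology; 10 rows, 2 duplicate pairs
TOY	BAX	BAX	involved_in	GO:0043065	TOY:0000001	IMP		P			protein	taxon:0000	20260101	TOY
TOY	BAX	BAX	involved_in	GO:0006915	TOY:0000001	IDA		P			protein	taxon:0000	20260101	TOY
TOY	BCL2	BCL2	involved_in	GO:0006916	TOY:0000001	IDA		P			protein	taxon:0000	20260101	TOY
TOY	BCL2	BCL2	involved_in	GO:0043066	TOY:0000001	ISO		P			protein	taxon:0000	20260101	TOY
TOY	BCL2	BCL2	involved_in	GO:0006916	TOY:0000002	IMP		P			protein	taxon:0000	20260101	TOY
TOY	TP53	TP53	involved_in	GO:0043065	TOY:0000001	IMP		P			protein	taxon:0000	20260101	TOY
TOY	TP53	TP53	involved_in	GO:0042981	TOY:0000001	IEA		P			protein	taxon:0000	20260101	TOY
TOY	TP53	TP53	involved_in	GO:0043065	TOY:0000003	ISO		P			protein	taxon:0000	20260101	TOY
TOY	CASP3	CASP3	involved_in	GO:0006915	TOY:0000001	IDA		P			protein	taxon:0000	20260101	TOY
TOY	MCL1	MCL1	involved_in	GO:0043066	TOY:0000001	IDA		P			protein	taxon:0000	20260101	TOY
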