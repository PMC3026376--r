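gene	hypothesis	G	M
IL-2	TH2	1/-1	
IL-2	Antigen Presentation		0
IL-2	Chemotaxis	1	
IL-2	Metastasis	1	
IL-2	Angiogenesis	1/-1	
IL-2	T Cell Activation	1/-1	1
IL-2	Cell Proliferation	1	1
IL-2	Apoptosis	1/-1	-1
IL-4	TH2	1/-1	1
IL-4	Antigen Presentation		1
IL-4	Chemotaxis	1	1
IL-4	Metastasis		
IL-4	Angiogenesis	1/-1	
IL-4	T Cell Activation		
IL-4	Cell Proliferation	1	1
IL-4	Apoptosis	-1	0
IL-6	TH2	1	
IL-6	Antigen Presentation		0
IL-6	Chemotaxis	1	-1
IL-6	Metastasis	1	0
IL-6	Angiogenesis	1	
IL-6	T Cell Activation	1	
IL-6	Cell Proliferation	1/-1	0
IL-6	Apoptosis	-1/1	
IL-8	TH2		
IL-8	Antigen Presentation		
IL-8	Chemotaxis	1	1
IL-8	Metastasis	1	1
IL-8	Angiogenesis	1	1
IL-8	T Cell Activation		
IL-8	Cell Proliferation	-1	-1
IL-8	Apoptosis	1	
IL-10	TH2	1	1
IL-10	Antigen Presentation		1
IL-10	Chemotaxis	1	
IL-10	Metastasis	1	0
IL-10	Angiogenesis		
IL-10	T Cell Activation	-1	
IL-10	Cell Proliferation	-1	-1
IL-10	Apoptosis	-1/1	-1
IL-13	TH2		1
IL-13	Antigen Presentation		
IL-13	Chemotaxis		
IL-13	Metastasis		
IL-13	Angiogenesis		
IL-13	T Cell Activation		
IL-13	Cell Proliferation	1	0
IL-13	Apoptosis		
IL-18	TH2	1	1
IL-18	Antigen Presentation		
IL-18	Chemotaxis		
IL-18	Metastasis		1
IL-18	Angiogenesis	1	1
IL-18	T Cell Activation	1	
IL-18	Cell Proliferation	1	1
IL-18	Apoptosis	1	1
IFNg	TH2		-1
IFNg	Antigen Presentation	-1	1
IFNg	Chemotaxis	1	
IFNg	Metastasis	1	
IFNg	Angiogenesis		
IFNg	T Cell Activation	1	
IFNg	Cell Proliferation	1/-1	-1
IFNg	Apoptosis	1	1
TGFb	TH2		1
TGFb	Antigen Presentation		
TGFb	Chemotaxis	1	
TGFb	Metastasis	1	
TGFb	Angiogenesis	1/-1	
TGFb	T Cell Activation		
TGFb	Cell Proliferation	-1	1
TGFb	Apoptosis	1/-1	-1
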