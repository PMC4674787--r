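stack	AU	AU	-0.9
stack	AU	UA	-1.1
stack	AU	CG	-2.2
stack	AU	GC	-2.1
stack	AU	GU	-0.6
stack	AU	UG	-1.4
stack	UA	AU	-1.3
stack	UA	UA	-0.9
stack	UA	CG	-2.4
stack	UA	GC	-2.1
stack	UA	GU	-1
stack	UA	UG	-1.3
stack	CG	AU	-2.1
stack	CG	UA	-2.1
stack	CG	CG	-3.3
stack	CG	GC	-2.4
stack	CG	GU	-1.4
stack	CG	UG	-2.1
stack	GC	AU	-2.4
stack	GC	UA	-2.2
stack	GC	CG	-3.4
stack	GC	GC	-3.3
stack	GC	GU	-1.5
stack	GC	UG	-2.5
stack	GU	AU	-1.3
stack	GU	UA	-1.4
stack	GU	CG	-2.5
stack	GU	GC	-2.1
stack	GU	GU	-0.5
stack	GU	UG	-0.2
stack	UG	AU	-1
stack	UG	UA	-0.6
stack	UG	CG	-1.5
stack	UG	GC	-1.4
stack	UG	GU	-0.2
stack	UG	UG	-0.5
param	bulge_open	.	3.8
param	bulge_ext	.	0.4
param	interior_open	.	1.2
param	interior_ext	.	0.4
param	max_bulge	.	15
param	terminal_au	.	0.45
param	pair_bonus	.	0
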