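# Nearest-neighbor RNA duplex parameters bundled with transitr.
# Watson-Crick stack dH/dS after Xia et al. (1998) Biochemistry 37:14719
# (1 M NaCl reference state).  G.U wobble stacks, initiation, terminal
# AU/GU penalty and the loop/bulge dG37 length table are bundled working
# values in the style of the Turner rules; wobble entries are approximate
# transcriptions and are NOT a verbatim copy of any published table.
# Only relative comparisons of dG values feed downstream predictions.
#
# Conventions: 'top' is a 5'->3' dinucleotide, 'bottom' the opposing
# dinucleotide written 3'->5' and aligned with 'top' (bottom[k] pairs
# top[k]).  dH kcal/mol, dS cal/(mol K), dG37 kcal/mol (= dH - 310.15*dS/1000,
# informational).  Symmetric orientations are expanded at load time.
# Loop rows give the dG37 penalty by total unpaired length; longer loops
# use Jacobson-Stockmayer extrapolation from the last entry.
type	key	dH	dS	dG37
stack	AA/UU	-6.82	-19.0	-0.93
stack	AU/UA	-9.38	-26.7	-1.10
stack	UA/AU	-7.69	-20.5	-1.33
stack	CU/GA	-10.48	-27.1	-2.08
stack	CA/GU	-10.44	-26.9	-2.11
stack	GU/CA	-11.40	-29.5	-2.24
stack	GA/CU	-12.44	-32.5	-2.35
stack	CG/GC	-10.64	-26.7	-2.36
stack	GG/CC	-13.39	-32.7	-3.26
stack	GC/CG	-14.88	-36.9	-3.42
stack	AG/UU	-3.21	-8.6	-0.54
stack	AU/UG	-8.81	-24.0	-1.37
stack	UG/AU	-7.01	-18.5	-1.27
stack	UU/AG	-6.01	-17.8	-0.49
stack	GG/CU	-8.33	-21.9	-1.54
stack	GU/CG	-12.59	-32.5	-2.51
stack	CG/GU	-5.61	-13.5	-1.42
stack	CU/GG	-12.11	-32.2	-2.12
stack	GG/UU	-10.51	-32.3	-0.49
stack	GU/UG	-5.00	-17.6	0.46
stack	UG/GU	-9.26	-27.9	-0.61
init	init	3.61	-1.5	4.08
terminal_au	terminal_au	3.72	10.5	0.46
loop	1	NA	NA	3.8
loop	2	NA	NA	2.8
loop	3	NA	NA	3.2
loop	4	NA	NA	3.6
loop	5	NA	NA	4.0
loop	6	NA	NA	4.4
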