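mutant	drug	log10_fold_change	screen_expectation
E571K	vosaroxin	2	resistant
A652T	ciprofloxacin	4.44	resistant
L926F	vosaroxin	2.1	resistant
G474A	ciprofloxacin	4.16	resistant
G551S	vosaroxin	3.67	resistant
I636M	ciprofloxacin	3.35	resistant
S654N	vosaroxin	3.92	resistant
P716H	ciprofloxacin	4.4	resistant
Q726H	vosaroxin	3.71	resistant
T858S	ciprofloxacin	3.83	resistant
V197M	vosaroxin	3.19	resistant
A484V	ciprofloxacin	3.87	resistant
A484T	vosaroxin	4.43	resistant
S729N	ciprofloxacin	2.66	resistant
A457T	vosaroxin	3.2	resistant
G737D	ciprofloxacin	4.44	resistant
A725E	vosaroxin	4.54	resistant
E430K	ciprofloxacin	2.31	resistant
G832S	vosaroxin	4	resistant
L531F	ciprofloxacin	3.46	resistant
A484V	vosaroxin	0.31	sensitive
V197M	vosaroxin	0.12	sensitive
A830V	ciprofloxacin	0.24	resistant
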