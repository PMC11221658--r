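region	W1	W2	W3	W4	W5
Dorsolateral prefrontal cortex	2	6	4	4	3
Medial prefrontal cortex	2	6	4	4	4
Orbital prefrontal cortex	2	6	2	3	4
Ventrolateral prefrontal cortex	0	6	4	4	4
Primary motor-somatosensory cortex	2	0	3	0	0
Primary motor (m1) cortex	0	6	1	3	4
Primary somatosensory (s1) cortex	0	6	0	3	4
Occipital neocortex	2	0	0	0	0
Primary visual (v1) cortex	0	6	4	3	4
Parietal cortex	1	0	0	0	0
Posterior inferior parietal cortex	0	6	4	3	4
Primary auditory (a1) cortex	0	6	4	3	4
Inferior temporal cortex	0	6	2	2	4
Superior temporal cortex	0	4	4	3	4
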