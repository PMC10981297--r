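variable	out_strength	in_strength
excessive_worry	0.10	0.32
uncontrollable_worry	0.17	0.33
restlessness	0.08	0.32
fatigue	0.23	0.50
difficulty_concentrating	0.14	0.32
irritability	0.00	0.19
muscle_tension	0.04	0.19
sleep_disturbance	1.41	0.00
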