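# calibrate_affinity scan: INSR-like layout, PC:PS:PIP2 80:10:10,
# default sim_config, 2 replicates per grid point, target window [4,6].
# Selected epsilon_elec = 16 (smallest grid value inside the window).
"epsilon_elec","mean_first_shell"
2,0.653333333333333
4,1.53833333333333
8,3.14083333333333
12,3.95166666666667
16,4.71166666666667
24,5.71083333333333
32,6.87916666666667
48,6.36333333333333
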