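# Physiological baseline: two identical 20 nm clefts, glutamate carrier.
[cleft1]
d_nm = 20
D_um2_per_ms = 0.33
V_mV = -4
T_kelvin = 310

[cleft2]
d_nm = 20
D_um2_per_ms = 0.33
V_mV = -4
T_kelvin = 310

[wall]
Fmax_N = 9.6e-12
x0_m = 2e-9
lC_m = -3e-10
wall_variant = anti_return

[sim]
dt_ns = 10
n_runs = 50000
t_max_ms = 5
x_start_nm = 0
interpolate_crossing = false
seed = 1
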