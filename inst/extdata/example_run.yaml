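model_variant: cell_elongation
preset: desk
signaling: 'off'
behavior_mode: uniform
mosaic_ratio: 1.0
seeds:
- 1
- 2
- 3
duration_mcs: 6000
window.start: 2000.0
window.end: 6000.0
sample_stride: 20
lattice: 200
spheroid_radius: 25.0
cell_width: 7
cpm.J.ECM.ECM: 0.0
cpm.J.ECM.tip: 0.4
cpm.J.ECM.stalk: 0.4
cpm.J.tip.tip: 0.8
cpm.J.stalk.tip: 0.8
cpm.J.stalk.stalk: 0.8
cpm.lambda_size: 1.0
cpm.lambda_length: 1.0
cpm.target_length: 40.0
cpm.mu: 1.0
cpm.connectivity_penalty: 100000.0
cpm.connectivity: yes
cpm.mcs_seconds: 30.0
cpm.site_um: 2.0
chemotaxis.lambda_c.tip: 10.0
chemotaxis.lambda_c.stalk: 10.0
chemotaxis.contact_inhibition: no
field.alpha: 0.00018
field.eps: 0.00018
field.D: 1.0e-13
field.dt: 2.0
field.dx: 2.0e-06
field.steps_per_mcs: 15
signaling.alpha_S: 0.008
signaling.k_S: 0.01
signaling.n_S: 2.0
signaling.gamma_S: 0.002
signaling.beta_Dc: 0.0002
signaling.beta_D: 0.0036
signaling.m_D: 2.0
signaling.gamma_D: 0.002
signaling.beta_N: 0.002
signaling.gamma_N: 0.002
signaling.k_c: 500.0
signaling.k_t: 500.0
signaling.d: 1.0
signaling.alpha_A: 0.002
signaling.k_A: 1.0
signaling.n_A: 2.0
signaling.gamma_A: 0.002
signaling.beta_Rc: 0.0002
signaling.beta_R: 0.0036
signaling.m_R: 2.0
signaling.gamma_R: 0.002
signaling.alpha_D_vegf: 0.004
signaling.k_D: 0.25
signaling.n_D: 2.0
signaling.V_ext: 1.0
signaling.nicd_threshold: 1.0
signaling.ode_dt: 3.0
signaling.iters_per_mcs: 10
morph.r: 2.0
morph.t: 5.0
morph.p: 25.0
morph.m: 15.0
persistence_mcs: 80.0
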