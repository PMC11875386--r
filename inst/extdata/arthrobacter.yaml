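# Decomposition rate parameters for Arthrobacter sp. 9R,
# calibrated on experimental growth and respiration curves.
# Rates in day^-1; beta dimensionless; k_dom in the carbon-mass
# unit of the pool states (gC per g when states are normalized).
rho: 0.2
mu: 0.5
beta: 0.55
v_som: 0.01
v_fom: 0.3
v_dom: 9.6
k_dom: 0.001
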