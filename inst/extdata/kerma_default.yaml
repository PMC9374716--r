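# Default flux-to-dose (KERMA) conversion factors, version 1.
#
# Group order matches materials_default.yaml: fast, epithermal, thermal.
#
# boron_factor:    Gy cm^2 per (ug/g 10B), from sigma(2200 m/s) = 3837 b and
#                  Q = 2.34 MeV deposited locally per capture.
# nitrogen_factor: Gy cm^2 per unit nitrogen mass fraction, from
#                  14N(n,p)14C sigma = 1.83 b, Q = 0.626 MeV.
# hydrogen_factor: Gy cm^2 per unit hydrogen mass fraction (elastic recoil,
#                  coarse group averages).
# photon_factor:   Gy cm^2 per MeV of photon energy fluence
#                  (mu_en/rho for soft tissue near 2.2 MeV).
# 1/v capture factors are concentrated in the thermal group.
version: 1
boron_factor:    [0.0, 0.0, 8.66e-14]
nitrogen_factor: [0.0, 0.0, 7.9e-12]
hydrogen_factor: [2.0e-10, 5.0e-12, 0.0]
photon_factor:   4.2e-13
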