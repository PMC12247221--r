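canonical,mass_offset,charge,variants
[M+H]+,1.00727646,1,M+H|MH+|M+H+|[M+H]
[M+Na]+,22.98921706,1,M+Na|MNa+|M+Na+|[M+Na]
[M+K]+,38.96315786,1,M+K|MK+|M+K+|[M+K]
[M+NH4]+,18.03382555,1,M+NH4|MNH4+|M+NH4+|[M+NH4]
[M+H-H2O]+,-17.00273965,1,M+H-H2O|M-H2O+H|[M-H2O+H]+|[M+H-H2O]
[M+H-NH3]+,-16.01927407,1,M+H-NH3|M-NH3+H|[M-NH3+H]+
[M]+,-0.00054858,1,M+|M|[M]
[M+2H]2+,2.01455292,2,M+2H|[M+2H]|M+2H2+
[M+H+Na]2+,23.99649352,2,M+H+Na|[M+H+Na]
[M+Li]+,7.01545542,1,M+Li|[M+Li]
[M+CH3OH+H]+,33.03349,1,M+CH3OH+H|M+MeOH+H|[M+MeOH+H]+
[M+ACN+H]+,42.03382555,1,M+ACN+H|M+CH3CN+H|[M+CH3CN+H]+
[M+2Na-H]+,44.97115766,1,M+2Na-H|[M+2Na-H]
[M+K-H2O]+,21.95314321,1,M+K-H2O|[M+K-H2O]
[M+DMSO+H]+,79.02121646,1,M+DMSO+H|[M+DMSO+H]
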