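# Tabulated chromophore spectra for near-infrared tissue oximetry.
# SYNTHETIC COMPILATION: approximate values written from standard published
# tabulations of adult human hemoglobin molar extinction (Moaveni-style
# compilations as redistributed in the diffuse-optics literature) and of
# pure-water absorption (Matcher/Hale-Querry-style), rounded and resampled
# to a uniform 10 nm grid. Intended for simulation and self-consistent
# analysis, not as a metrological reference.
# Columns:
#   wavelength_nm           wavelength / nm
#   eps_hbo2_molar_log10    HbO2 molar decadic extinction / cm^-1 M^-1
#   eps_hb_molar_log10      Hb   molar decadic extinction / cm^-1 M^-1
#   mua_water_cm1           water absorption coefficient (ln based) / cm^-1
#                           at unit volume fraction
# Conversion used by the loader: eps[cm^-1 uM^-1, ln] =
#   eps_molar_log10 * ln(10) * 1e-6.
wavelength_nm,eps_hbo2_molar_log10,eps_hb_molar_log10,mua_water_cm1
650,368,3750,0.0034
660,320,3227,0.0039
670,294,2795,0.0043
680,278,2408,0.0047
690,276,2052,0.0052
700,290,1794,0.0060
710,314,1540,0.0076
720,342,1326,0.0107
730,390,1102,0.0169
740,446,1116,0.0250
750,518,1405,0.0260
760,586,1549,0.0256
770,650,1312,0.0243
780,710,1075,0.0234
790,756,891,0.0228
800,816,762,0.0226
810,864,717,0.0239
820,916,693,0.0260
830,974,694,0.0291
840,1022,692,0.0340
850,1058,691,0.0431
860,1092,694,0.0500
870,1128,704,0.0556
880,1154,726,0.0605
890,1178,740,0.0645
900,1198,762,0.0679
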