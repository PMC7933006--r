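# trpflux default kinetic parameters, version 1.
# Units: concentration in model units (mM-equivalent), time in hours.
# Designed so the normoxic baseline runs below saturation everywhere
# (steady-state substrate within ~10x of Km), the kynurenine pathway
# carries ~95% of intracellular Trp consumption, downstream capacities
# exceed their steady-state influx, and the empty (all-zero) state is
# dynamically unstable so the positive steady state is the attractor.
oxygen_level: 1.0
reactions:
  R_LAT1:
    vmax: 20.0
    km: {Trp_ext: 20.0, Kyn: 0.1}
    keq_bias: 1.0
  R_LAT2:
    vmax: 20.0
    km: {Trp_ext: 20.0, Kyn: 0.1}
    keq_bias: 1.0
  R_TDO2:
    vmax: 20.0
    km: {Trp: 2.0}
    km_oxygen: 0.1
  R_KAT:
    vmax: 4.0
    km: {Kyn: 1.0}
  R_KMO:
    vmax: 8.0
    km: {Kyn: 1.0}
    km_oxygen: 0.1
  R_KYNU_a:
    vmax: 2.4
    km: {Kyn: 1.0}
  R_KYNU_b:
    vmax: 6.0
    km: {HKyn3: 1.0}
  R_HAAO:
    vmax: 6.0
    km: {HAA3: 1.0}
    km_oxygen: 0.1
  R_QPRT:
    vmax: 6.0
    km: {Quin: 1.0}
  R_DDC_trp:
    vmax: 1.0
    km: {Trp: 10.0}
  R_INMT_1:
    vmax: 0.5
    km: {Trypta: 0.5}
  R_INMT_2:
    vmax: 1.0
    km: {MeTrypta: 0.5}
  R_TPH1:
    vmax: 0.4
    km: {Trp: 10.0}
    km_oxygen: 0.1
  R_DDC_5htp:
    vmax: 2.0
    km: {HTP5: 1.0}
  R_IL4I1:
    vmax: 0.4
    km: {Trp: 10.0}
    km_oxygen: 0.1
  R_clr_KynA:
    kclear: 1.0
  R_clr_AA:
    kclear: 1.0
  R_clr_NaMN_sinkpool:
    kclear: 1.0
  R_clr_Trypta_MAO:
    kclear: 2.0
  R_clr_DMT:
    kclear: 1.0
  R_clr_Serotonin:
    kclear: 1.0
  R_clr_I3P:
    kclear: 1.0
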