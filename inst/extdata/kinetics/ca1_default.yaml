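# Default kinetic scheme: CA1-pyramidal-flavored Hodgkin-Huxley channels.
#
# Provenance: an independent transcription of the Migliore-family CA1
# pyramidal channel set (transient Na as m^3 h, delayed-rectifier K,
# A-type K with slow inactivation, hyperpolarization-activated h current),
# recast into the package's sigmoid/bell gate parameterization. Half
# activation voltages and slopes follow the published CA1 family; time
# constants are smooth bell fits chosen once for standard CA1 physiology
# (resting potential near -70 mV, somatic spike threshold near -50 mV,
# overshooting axonal action potentials). The half-activation of the
# delayed rectifier (+13 mV) follows the CA1 literature; it places the cell
# in the integrator excitability class (see the methods vignette for what
# this implies for near-threshold firing rates).
# Reversal potentials are conventional values for these currents and are
# deliberately kept here, never hard-coded in computation.
#
# Units: mV for voltages, ms for time constants. Gate steady state is
# 1/(1 + exp((vhalf - v)/k)) (k < 0 gives inactivation/hyperpolarization
# activation); bell time constants are min + amp/(exp((v-vmax)/k1) +
# exp(-(v-vmax)/k2)).
name: ca1-default
version: "1"
reversals:
  na: 55.0
  k: -90.0
  h: -30.0
channels:
  na:
    reversal: na
    gates:
      - name: m
        power: 3
        inf: {vhalf: -38.0, k: 7.2}
        tau: {type: bell, min: 0.05, amp: 0.8, vmax: -38.0, k1: 15.0, k2: 15.0}
      - name: h
        power: 1
        inf: {vhalf: -50.0, k: -4.0}
        tau: {type: bell, min: 0.5, amp: 7.5, vmax: -50.0, k1: 15.0, k2: 15.0}
  kdr:
    reversal: k
    gates:
      - name: n
        power: 1
        inf: {vhalf: 13.0, k: 8.8}
        tau: {type: bell, min: 1.5, amp: 3.0, vmax: 13.0, k1: 25.0, k2: 25.0}
  ka:
    reversal: k
    gates:
      - name: a
        power: 1
        inf: {vhalf: 11.0, k: 12.0}
        tau: {type: bell, min: 0.2, amp: 1.0, vmax: 11.0, k1: 20.0, k2: 20.0}
      - name: b
        power: 1
        inf: {vhalf: -56.0, k: -8.0}
        tau: {type: bell, min: 5.0, amp: 20.0, vmax: -56.0, k1: 20.0, k2: 20.0}
  h:
    reversal: h
    gates:
      - name: l
        power: 1
        inf: {vhalf: -81.0, k: -8.0}
        tau: {type: bell, min: 15.0, amp: 40.0, vmax: -81.0, k1: 20.0, k2: 20.0}
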