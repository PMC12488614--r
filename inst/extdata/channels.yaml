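# Voltage-gated channel registry.
#
# One document per channel. Steady-state and time-constant curves are stored
# as named parameter sets for a small set of functional forms (see
# eval_ss_form() / eval_tau_form()):
#   ss   boltzmann:      1 / (1 + exp((vhalf - v)/k))        (k < 0: inactivation)
#   tau  constant:       tau
#        bell:           base + amp * exp(-((v - vpeak)/width)^2)
#        recip2exp:      c0 + 1 / (exp(-(v - v1)/b1) + exp((v - v2)/b2))
#        texp_piecewise: v < vsplit : exp((v - v1)/b1)
#                        v >= vsplit: c0 + exp(-(v - v2)/b2)
#        linclip:        max(tmin, a * (v - v0))
#
# tref is the temperature (degC) at which the tau parameters are stated; the
# q10 correction tau(T) = tau(tref) / q10^((T - tref)/10) is applied per gate.
# Time constants are in ms, voltages in mV, densities in S/cm2.
#
# Na, KDR and KA follow the Migliore-type CA1 scheme family (Borg-Graham
# Boltzmann equivalents for the voltage dependences; KA inactivation tau is
# the linear-clipped form of that scheme). The distal KA model is the
# proximal one with a -12 mV activation V1/2 offset. h is a Magee-style
# single activation gate (somatic V1/2 -82 mV; the somato-apical V1/2
# gradient is applied as a per-compartment shift). CaT is the canonical
# low-threshold T-type scheme (Huguenard-McCormick/Destexhe closed forms)
# with a GHK current law.
Na:
  current: ohmic
  erev: 55
  gates:
    - name: "m"
      exponent: 3
      ss:  {form: boltzmann, vhalf: -30, k: 7.2}
      tau: {form: bell, base: 0.1, amp: 0.5, vpeak: -30, width: 25}
      q10: 3
      tref: 24
    - name: "h"
      exponent: 1
      ss:  {form: boltzmann, vhalf: -52, k: -4}
      tau: {form: bell, base: 0.5, amp: 6, vpeak: -55, width: 20}
      q10: 3
      tref: 24
KDR:
  current: ohmic
  erev: -90
  gates:
    - name: "n"
      exponent: 1
      ss:  {form: boltzmann, vhalf: 13, k: 8.8}
      tau: {form: bell, base: 1, amp: 10, vpeak: -30, width: 30}
      q10: 3
      tref: 24
KA_prox:
  current: ohmic
  erev: -90
  gates:
    - name: "a"
      exponent: 1
      ss:  {form: boltzmann, vhalf: 11, k: 18}
      tau: {form: bell, base: 0.2, amp: 1.0, vpeak: -30, width: 30}
      q10: 3
      tref: 24
    - name: "b"
      exponent: 1
      ss:  {form: boltzmann, vhalf: -56, k: -8.8}
      tau: {form: linclip, tmin: 2, a: 0.26, v0: -50}
      q10: 1
      tref: 34
KA_dist:
  current: ohmic
  erev: -90
  gates:
    - name: "a"
      exponent: 1
      ss:  {form: boltzmann, vhalf: -1, k: 18}
      tau: {form: bell, base: 0.2, amp: 1.0, vpeak: -30, width: 30}
      q10: 3
      tref: 24
    - name: "b"
      exponent: 1
      ss:  {form: boltzmann, vhalf: -56, k: -8.8}
      tau: {form: linclip, tmin: 2, a: 0.26, v0: -50}
      q10: 1
      tref: 34
h:
  current: ohmic
  erev: -30
  gates:
    - name: "s"
      exponent: 1
      ss:  {form: boltzmann, vhalf: -82, k: -8}
      tau: {form: bell, base: 8, amp: 42, vpeak: -82, width: 25}
      q10: 1
      tref: 34
CaT:
  current: ghk
  valence: 2
  gates:
    - name: "m"
      exponent: 2
      ss:  {form: boltzmann, vhalf: -57, k: 6.2}
      tau: {form: recip2exp, c0: 0.612, v1: -132, b1: 16.7, v2: -16.8, b2: 18.2}
      q10: 2.5
      tref: 24
    - name: "h"
      exponent: 1
      ss:  {form: boltzmann, vhalf: -81, k: -4}
      tau: {form: texp_piecewise, vsplit: -81, v1: -467, b1: 66.6, c0: 28, v2: -22, b2: 10.5}
      q10: 3
      tref: 24
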