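# Demo scenario: eight cohort years of a polar fjord littoral observatory.
# Half the cohort years are dominated by injected warm events ("Atlantic"
# phases), the other half by cold events ("Arctic" phases); community
# abundance is positively coupled to cohort temperature day-degrees.
seed: 42
scenario:
  start: "2012-08-01"
  end: "2020-07-31"
  temp_mean: 3.0
  temp_amplitude: 3.5
  temp_phase: 220
  temp_ar1: 0.7
  temp_noise_sd: 0.5
  sal_mean: 34.0
  sal_amplitude: 0.8
  sal_phase: 50
  sal_ar1: 0.7
  sal_noise_sd: 0.15
  dispersion: 1.5
  coupling_beta: 0.8
  effort_dropout: 0.1
  injected_events:
    - {variable: temperature, start: "2013-01-10", duration: 18, amplitude: 2.5}
    - {variable: temperature, start: "2014-02-05", duration: 25, amplitude: 2.0}
    - {variable: temperature, start: "2014-11-20", duration: 20, amplitude: 2.8}
    - {variable: temperature, start: "2015-12-10", duration: 24, amplitude: -2.4}
    - {variable: temperature, start: "2017-01-15", duration: 30, amplitude: 2.2}
    - {variable: temperature, start: "2018-01-20", duration: 16, amplitude: 2.6}
    - {variable: temperature, start: "2019-02-01", duration: 28, amplitude: -2.0}
    - {variable: temperature, start: "2019-11-10", duration: 35, amplitude: -2.5}
    - {variable: salinity, start: "2013-03-01", duration: 14, amplitude: 0.6}
    - {variable: salinity, start: "2016-02-10", duration: 20, amplitude: -0.7}
events:
  min_duration: 5
  max_gap: 0
  baseline: threshold
climatology:
  window_halfwidth: 5
  smooth_span: 31
biotic:
  effort_floor: 48
  min_duration_weeks: 1
stats:
  ranking_key: net_sum
  exclusion_variants:
    no_jellyfish: [jellyfish]
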