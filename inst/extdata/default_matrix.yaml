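parameters:
  ctd90:
    increase:
      no_effect: 6.48608660865788
      mild: 30.690761981340138
      strong: 54.895437354022391
      points:
        mild: 1.0
        strong: 3.0
    decrease:
      no_effect: -6.48608660865788
      mild: -20.465596023917577
      strong: -34.445105439177269
      points:
        mild: 1.0
        strong: 3.0
  br:
    increase:
      no_effect: 8.896103896103895
      mild: 43.896103896103895
      strong: 78.896103896103895
      points:
        mild: 1.0
        strong: 2.0
    decrease:
      no_effect: -8.896103896103895
      mild: -32.5
      strong: -56.103896103896105
      points:
        mild: 1.0
        strong: 2.0
  amp:
    increase:
      no_effect: 6.623007265575803
      mild: 20.812064526091703
      strong: 35.001121786607605
      points:
        mild: 1.0
        strong: 2.0
    decrease:
      no_effect: -6.623007265575803
      mild: -34.308371781198666
      strong: -61.993736296821531
      points:
        mild: 1.0
        strong: 2.0
beat_stop_zones:
  low:
    upper: 0.5
    points: 1.0
  mid:
    points: 2.0
  full:
    points: 4.0
fibrillation_points: 4.0
label_ranges:
  'no':
  - 0.0
  - 0.0
  low:
  - 1.0
  - 2.0
  high:
  - 3.0
  - '.inf'
ead_override: yes
coverage_p: 0.9
confidence_gamma: 0.95
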