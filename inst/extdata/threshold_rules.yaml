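# Packaged threshold rules: quantitative criteria that map a measured ratio or
# quantity onto the 1-5 metric scale. Boundary convention: an interval edge
# belongs to the interval closer to the scale midpoint (level 3), so the
# level-3 band is closed and the extreme bands are open.
#
# Encoding: `breakpoints` are the 4 interior edges in increasing order;
# `boundary_to_upper[i]` is true when a value equal to breakpoints[i] falls in
# the UPPER of the two adjacent level bands.
rules:
  - metric_id: crew_earnings_vs_regional
    name: Crew Earnings Compared to Regional Average Earnings
    variable: ratio of annual crew earnings from fishing to regional average earnings
    units: ratio
    domain_min: 0.0
    direction: benefit
    breakpoints: [0.5, 0.9, 1.1, 1.5]
    boundary_to_upper: [true, true, false, false]
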