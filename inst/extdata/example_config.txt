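# spotseg run configuration: slide layout and algorithm parameters.
# Layout of the example synthetic slide (2 x 2 groups of 8 x 8 spots).
groups_nx = 2
groups_ny = 2
spots_per_group_nx = 8
spots_per_group_ny = 8
spot_pitch_px = 28        # center-to-center spot distance

# Algorithm parameters (defaults shown; all optional)
t_f = 50                  # shock-filter iterations
gauss_k = 3               # smoothing kernel width (px)
gauss_sigma = 5           # smoothing kernel sd (px)
thr_frac = 0.30           # border threshold, fraction of mean profile
ellipse_margin_px = 3     # exclusion ellipse radius increment
lowess_span = 0.20        # lowess window fraction
upreg_threshold = 2       # up-regulation ratio threshold (strict >)
rotation_search_deg = 5   # rotation search half-range (0 disables)
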