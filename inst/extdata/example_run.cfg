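# ecobnet pipeline configuration: simulate a synthetic survey, learn the
# bootstrap consensus network, and run a substrate contrast.
seed = 11
outdir = ecobnet_run

# synthetic community (omit `input`/`specs` to trigger simulation;
# point them at a CSV + spec file to analyse real data instead)
n_taxa = 6
n_edges = 7
lambda = 0.8
n_photos = 1000
photos_per_event = 25

# analysis scale and pre-filters
scale = photo
occupancy_threshold = 0.3333333
chi_p_threshold = 0.25

# structure search and bootstrap
iterations = 20000
restarts = 50
ess = 1
max_parents = 3
B = 100
frac = 0.95

# inference contrast: force the substrate from its first to its last state
infer_source = substrate
infer_from = 0
infer_to = 2
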