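# Default pipeline configuration: analyse events.csv / categories.csv in the
# working directory with the package's reference parameters.
events: events.csv
categories: categories.csv
output_dir: forumdyn_out
session_gap_threshold: 60   # minutes of inactivity that end a session
min_views: 100              # activity filter for the clustering stage
k: auto                     # elbow-selected cluster count
k_range: [2, 15]
restarts: 10
periodicity_min_events: 50
periodicity_dominance_ratio: 2.0
periodicity_min_power_fraction: 0.10
rr_min: 1.0                 # drop category links weaker than independence
seed: 42
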