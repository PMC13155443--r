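# Default labelsieve run configuration.
# Any key may be overridden; unknown keys are rejected.

# --- synthetic dataset ---
dataset: nanopore          # nanopore | stand_in
# nanopore generator: three balanced classes (empty / single / double)
sample_rate: 250000        # samples per second; 1-s segments -> 250,000 points
segment_s: 1
duration_s: 120            # seconds per class -> 120 images per class
render_width: 32
render_height: 32
# stand_in generator (used when dataset: stand_in)
n_classes: 10
per_class: 100
image_size: 24
jitter_sd: 1
noise_sd: 0.05

# --- injection ---
count: 20                  # labels to flip

# --- detection ---
n_subsets: 10
classifiers: ["tiny_cnn:16", "tiny_cnn:32", "tiny_cnn:64",
              "tiny_cnn:128", "tiny_cnn:256"]
epochs: 15
learning_rate: 0.05
momentum: 0.9
batch_size: 32
delta: 0.5
rules: ["MF", "CF"]
shuffle_folds: true

# --- sweep / baselines ---
deltas: [0.5, 0.6, 0.7, 0.8, 0.9]
knn_k: 5
test_fraction: 0.25
pca_components: 2

seed: 1
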