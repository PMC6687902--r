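# Shipped synthetic fixtures

Small pre-generated evoked-response datasets from the package's own
generator (`generate_dataset()`), under the default attention-network
scenario (`default_scenario()`: true modulations 0, +0.1, -0.4, -0.4 on
effects 1-4). All values are synthetic; seeds are recorded in the
`*_truth.json` sidecars so every file can be regenerated bit-for-bit:

- `synthetic_noiseless_*`: infinite SNR, seed 11
- `synthetic_10db_*`: 10 dB whole-dataset SNR, seed 12
- `network.yaml`: the five-source network specification

Regenerate with, e.g.:

```r
net <- read_network("network.yaml")
truth <- read_ground_truth("synthetic_noiseless_truth.json", net)
ds <- generate_dataset(net, truth$params, snr_db = truth$snr_db,
                       seed = truth$seed)
```
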