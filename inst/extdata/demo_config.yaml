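# Demo pipeline configuration: five-channel synthetic benchmark recording.
input: inst/extdata/mvar5_demo.csv
out_dir: epitarget_demo_out
method: dtf-sa
band: [31, 80]
n_surr: 50
grid0: [0.1, 0.3, 0.5]
grid1: [0.6, 0.8, 1.0]
grid_realizations: 20
n_realizations: 50
seed: 11
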