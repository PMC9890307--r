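# pooled counts of the 2019 national village survey behind the example
# burden table: participants examined and podoconiosis cases diagnosed
cases: 16
examined: 6228
villages: 48
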