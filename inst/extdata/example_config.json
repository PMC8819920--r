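{
  "reads": "simulated_reads.fastq",
  "out_dir": "pipeline_out",
  "seed": 500,
  "expected_cells": 10,
  "adapter": "CTACACGACGCTCTTCCGATCT",
  "barcode_len": 16,
  "umi_len": 10,
  "polya_len": 20,
  "splint_umi_len": 12,
  "splint_flanks": ["ACTTGCCTGTCG", "CGTAATGCTCTG"],
  "umi_max_edits": 1
}
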