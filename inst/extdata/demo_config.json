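{
  "genome": {
    "chrom_lengths": {"chr1": 800000, "chr2": 500000},
    "genes": [
      {"chrom": "chr1", "start": 20000, "len": 3000, "introns": 2},
      {"chrom": "chr1", "start": 120000, "len": 3000, "introns": 4},
      {"chrom": "chr1", "start": 420000, "len": 2500, "introns": 1},
      {"chrom": "chr2", "start": 60000, "len": 3000, "introns": 3},
      {"chrom": "chr2", "start": 300000, "len": 2500, "introns": 0}
    ],
    "tandem_clusters": [
      {"chrom": "chr1", "start": 80000, "unit_len": 4000, "copies": 2},
      {"chrom": "chr1", "start": 250000, "unit_len": 3000, "copies": 3},
      {"chrom": "chr2", "start": 150000, "unit_len": 4000, "copies": 2}
    ],
    "interchrom_pairs": [
      {"chrom1": "chr1", "start1": 500000, "chrom2": "chr2", "start2": 400000, "len": 3500}
    ],
    "tes": [
      {"chrom": "chr1", "start": 350000, "len": 2000},
      {"chrom": "chr1", "start": 600000, "len": 2000},
      {"chrom": "chr2", "start": 200000, "len": 2000}
    ],
    "ssrs": [
      {"chrom": "chr1", "start": 700000, "unit": "AT", "copies": 60},
      {"chrom": "chr2", "start": 100000, "unit": "CAG", "copies": 40}
    ],
    "gaps": [
      {"chrom": "chr1", "start": 180000, "len": 4000},
      {"chrom": "chr2", "start": 250000, "len": 3000}
    ],
    "collapse": [
      {"type": "tandem", "id": 1},
      {"type": "tandem", "id": 2},
      {"type": "interchrom", "id": 1}
    ],
    "coverage": 46,
    "read_length": 100,
    "seed": 7
  },
  "params": {
    "bin_size": 100,
    "q_max": 0.08,
    "q0_max": 0.5,
    "low": 0.72,
    "high": 1.76,
    "min_identity": 95,
    "n_datasets": 10,
    "n_perm": 200,
    "window": 100000
  },
  "seed": 7
}
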