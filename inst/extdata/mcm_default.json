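{
  "name": "MCM-like synthetic community",
  "version": "1.0",
  "comment": "Synthetic stand-in for the ten-species metagenomic control material. Genome sizes, rrn copy numbers, GC fractions and abundances are chosen inside the published ranges (1.85-6.26 Mb, 4-8 rrn copies, 33%-67% GC, ~100 to >50,000 genome copies/uL, abundance rank order preserved within each Gram subgroup); the exact per-species values are not authoritative.",
  "members": [
    {"name": "Neisseria meningitidis",   "genus": "Neisseria",     "family": "Neisseriaceae",      "order": "Neisseriales",     "subgroup": "gram_negative", "genome_length": 2272000, "rrn_copies": 4, "gc_fraction": 0.52,  "true_copies_per_ul": 51000},
    {"name": "Klebsiella pneumoniae",    "genus": "Klebsiella",    "family": "Enterobacteriaceae", "order": "Enterobacterales", "subgroup": "gram_negative", "genome_length": 5306000, "rrn_copies": 8, "gc_fraction": 0.57,  "true_copies_per_ul": 18000},
    {"name": "Escherichia coli",         "genus": "Escherichia",   "family": "Enterobacteriaceae", "order": "Enterobacterales", "subgroup": "gram_negative", "genome_length": 4642000, "rrn_copies": 7, "gc_fraction": 0.51,  "true_copies_per_ul": 7500},
    {"name": "Pseudomonas aeruginosa",   "genus": "Pseudomonas",   "family": "Pseudomonadaceae",   "order": "Pseudomonadales",  "subgroup": "gram_negative", "genome_length": 6260000, "rrn_copies": 4, "gc_fraction": 0.67,  "true_copies_per_ul": 2500},
    {"name": "Acinetobacter baumannii",  "genus": "Acinetobacter", "family": "Moraxellaceae",      "order": "Pseudomonadales",  "subgroup": "gram_negative", "genome_length": 3977000, "rrn_copies": 6, "gc_fraction": 0.39,  "true_copies_per_ul": 100},
    {"name": "Streptococcus pneumoniae", "genus": "Streptococcus", "family": "Streptococcaceae",   "order": "Lactobacillales",  "subgroup": "gram_positive", "genome_length": 2101000, "rrn_copies": 4, "gc_fraction": 0.40,  "true_copies_per_ul": 12000},
    {"name": "Staphylococcus aureus",    "genus": "Staphylococcus","family": "Staphylococcaceae",  "order": "Bacillales",       "subgroup": "gram_positive", "genome_length": 2821000, "rrn_copies": 5, "gc_fraction": 0.33,  "true_copies_per_ul": 5000},
    {"name": "Streptococcus pyogenes",   "genus": "Streptococcus", "family": "Streptococcaceae",   "order": "Lactobacillales",  "subgroup": "gram_positive", "genome_length": 1852000, "rrn_copies": 6, "gc_fraction": 0.39,  "true_copies_per_ul": 1800},
    {"name": "Streptococcus agalactiae", "genus": "Streptococcus", "family": "Streptococcaceae",   "order": "Lactobacillales",  "subgroup": "gram_positive", "genome_length": 2200000, "rrn_copies": 7, "gc_fraction": 0.36,  "true_copies_per_ul": 700},
    {"name": "Enterococcus faecalis",    "genus": "Enterococcus",  "family": "Enterococcaceae",    "order": "Lactobacillales",  "subgroup": "gram_positive", "genome_length": 3013000, "rrn_copies": 4, "gc_fraction": 0.375, "true_copies_per_ul": 250}
  ]
}
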