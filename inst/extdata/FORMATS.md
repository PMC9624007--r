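# File formats

All formats are plain text; the files in this directory are a worked
example (3 random 4 kb genomes, weighted MinHash screen with M = 5 and a
constant-f = 2 sketch tree, 9 simulated 500 bp reads at 1% error).

## Screen container (`example_screen.txt`)

Versioned key-value header, then one block per genome, then the optional
sketch tree. Written by `save_screen()`, read by `load_screen()`.

    #readscreen_screen<TAB>v1        format version; rejected if unknown
    #k ... #hash_seed ...            the screen_params that built it
    #identity_hash 0|1               identity-mode screens are flagged and
                                     must never be mixed with production ones
    #method, #sublist_length, #weight_multiplier
    #n_genomes N
    >genome_id<TAB>genome_size<TAB>n_hashes
    hash[<TAB>weight]                one decimal hash per line; weighted
                                     MinHash adds the weight column
    @positions<TAB>n                 order MinHash only: position<TAB>hash
                                     lines in genome order (sublists are
                                     reconstructed from these and L)
    #tree<TAB>downsample=...<TAB>f=...<TAB>rng_seed=...
    #tree_newick<TAB>(...)           topology with genome_id leaf labels
    @node<TAB>id<TAB>children|leaf<TAB>genome_ids<TAB>height<TAB>n_hashes
    hash...                          internal nodes list their stored
                                     hashes; leaves reuse their sketch

Hashes are integral doubles < 2^53 printed in decimal, so round-trips are
exact. Editing is local: removing a genome's block (and re-annotating
weights for weighted MinHash) reproduces a screen built without it.

## Reads / genomes

Standard FASTA (optionally gzipped on input); record ids are the first
whitespace-delimited token, sequences are uppercased on read.

## Ground truth (`example_truth.tsv`)

TSV: `read_id  genome_id  start  strand  n_errors`, start 0-based on the
forward strand, `n_errors` the substitutions injected after strand choice.

## Classification report (`example_report.tsv`)

`#`-prefixed summary lines (read counts, accuracy and per-genome table
when ground truth was supplied, parameter echo), then a TSV body:
`read_id  predicted  score  n_shared  tied_with  status` with optional
`group`. `status` is `classified`, `tie_stopped` (tree tie-stop mode;
`tied_with` then lists the subtree's genomes) or `unclassified`.
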