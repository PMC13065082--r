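# cgrnet

Alignment-free phage host classification from genome sequence alone.

Bacteriophages adapt to the codon usage and oligonucleotide composition of
their bacterial hosts, so phages infecting the same host tend to share k-mer
signatures. `cgrnet` turns each phage genome into a fixed-size, three-channel
image built on the Chaos Game Representation (CGR) and classifies the host
taxon (species, genus or family level) with a small convolutional neural
network. It is aimed at viromics workflows where assembled phage contigs must
be assigned a candidate host without alignment to a reference database.

## The representation

The CGR embeds a DNA sequence S = a<sub>1</sub>a<sub>2</sub>…a<sub>L</sub>
in the unit square by the midpoint iteration

> CGR<sub>i</sub> = ½ (CGR<sub>i−1</sub> + corner(a<sub>i</sub>)),  CGR<sub>0</sub> = (0.5, 0.5),

with each nucleotide assigned a corner — by default A=(0,0), C=(0,1),
G=(1,1), T=(1,0). Every point with the same final k letters lands in the
same 2<sup>−k</sup> × 2<sup>−k</sup> sub-square, so the unit square
partitions into a 2<sup>k</sup> × 2<sup>k</sup> grid of k-mer cells. Each
genome becomes a 3 × 2<sup>k</sup> × 2<sup>k</sup> tensor:

* **F1** — the count N<sub>w</sub> of each k-mer w (the classic frequency
  CGR);
* **F2 / F3** — the mean x and mean y coordinate of the trajectory points at
  which w ends, i.e. where in the genome's CGR the occurrences of w sit on
  average. Absent words are 0.

Channels are min-max normalized per sequence and fed to a CNN: two 5×5
convolution blocks (64 and 128 channels, stride 1, padding 2, ReLU, 2×2 max
pooling), a 512-unit fully connected layer and a softmax over host taxa,
trained with Adam (learning rate 0.001) on the categorical cross-entropy.
For the default k = 7 the activation chain is
(3,128,128) → (64,128,128) → (64,64,64) → (128,64,64) → (128,32,32).

The package also computes the standard multi-class metrics (accuracy, macro
precision/recall/F1, top-k accuracy, confusion matrices), exports pairwise
cosine distances over flattened tensors (order F1, F2, F3) for external
Neighbor-Joining tree building, and ships a seeded Markov-chain simulator of
class-conditioned phage-like sequences so the whole pipeline can be
exercised offline.

## Worked example

The 10-mer `AGTCGTTACA` at k = 2 is small enough to follow by hand:

```r
library(cgrnet)

p <- kmer_average_positions("AGTCGTTACA", 2)
p$counts[p$counts > 0]
#> AC AG CA CG GT TA TC TT
#>  1  1  1  1  2  1  1  1

round(p$mean_x[c("AG", "GT", "TT", "TA")], 8)
#>        AG        GT        TT        TA
#> 0.62500000 0.83203125 0.92578125 0.46289062
```

`GT` occurs twice (positions 3 and 6); its mean x is the average of the two
trajectory points 0.8125 and 0.8515625, i.e. 0.83203125. The tensor places
that value at GT's grid cell:

```r
tz <- build_feature_tensor("AGTCGTTACA", 2, normalize = FALSE)
cell <- kmer_cell_index("GT", 2)   # row 2, col 3 (0-based, row 0 = top)
tz[cell["row"] + 1, cell["col"] + 1, ]
#>      freq    mean_x    mean_y
#> 2.0000000 0.8320312 0.3632812
```

A full pipeline on simulated data, from the shell (`exec/cgrnet` is
installed with the package):

```sh
cgrnet simulate  --classes 5 --per-class 50 --length 2000 --seed 7 \
                 --out-fasta phages.fasta --out-labels hosts.tsv
cgrnet featurize --fasta phages.fasta --k 3 --out tensors.rds
cgrnet train     --tensors tensors.rds --labels hosts.tsv --out model.rds --seed 7
cgrnet predict   --model model.rds --tensors tensors.rds --out calls.tsv
cgrnet evaluate  --predictions calls.tsv --labels hosts.tsv --out metrics.json
cgrnet distmat   --tensors tensors.rds --out phages.phy
```

`metrics.json` holds accuracy, macro precision/recall/F1 and top-k accuracy;
`phages.phy` is a square PHYLIP cosine-distance matrix ready for an external
Neighbor-Joining tool. The same steps are available as R functions
(`make_class_specs()`/`sample_sequences()`, `featurize()`, `cgrnet()`,
`predict()`, `metric_report()`, `pairwise_distances()`), with `cgrnet()`
returning a fitted-model object supporting `print`, `summary`, `coef`,
`plot` and `predict`.

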