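Package: cgrnet
Title: Phage Host Classification from Chaos Game Representation Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Alignment-free prediction of bacteriophage host taxa from genome
    sequence alone. Each genome is encoded as a three-channel 2^k x 2^k
    feature tensor combining k-mer frequencies with the mean x/y positions at
    which each k-mer ends in the Chaos Game Representation (CGR) of the
    sequence. A compact convolutional neural network (two 5x5 convolution
    blocks with ReLU and 2x2 max pooling, a 512-unit fully connected layer and
    a softmax output, trained with Adam on the cross-entropy loss) classifies
    tensors into host taxa. The package also provides multi-class evaluation
    metrics (accuracy, macro precision/recall/F1, top-k accuracy, confusion
    matrices), cosine-distance matrices over flattened tensors for external
    phylogenetic tree building, a seeded Markov-chain generator of
    class-conditioned phage-like sequences for offline testing, and a small
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    methods,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
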