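# liwcnn

Lexicon-weighted convolutional triage of mental-health posts.

Peer-support forums triage posts into four escalating risk categories —
**green** (no concern), **amber** (possible concern), **red** (serious,
needs a moderator), **crisis** (strong self-harm tendency).  `liwcnn`
classifies posts into these categories with a convolutional text model
whose input word vectors are scaled by attention weights derived from a
LIWC-style lexicon: word classes (death words, friend words, anger words,
…) that are used very differently across the four categories boost the
vectors of their member words.

## The method

For word class *l* and category *c*, the class frequency is the fraction
of tokens in category-*c* posts matching *l*:

    TF(l, c) = Σᵢ Σⱼ 1_l(tⁱⱼ) · 1_c(pᵢ)  /  Σᵢ nᵢ · 1_c(pᵢ)

Each class's row is normalized by its peak, TF′(l, c) = TF(l, c) / max_c
TF(l, c), and scored by the spread δ_l = √Σ_c (TF′(l, c) − μ_l)², where
μ_l is the mean of the four normalized values.  The *k* classes with the
largest δ (default k = 28) are selected, and each token *i* receives the
attention weight

    aᵢ = exp(δ*ᵢ) / Σ_{l ∈ selected} exp(δ_l) + 1        if i matches a selected class
    aᵢ = 1                                               otherwise

with δ\*ᵢ the largest δ among the token's selected classes.  The post's
word-vector matrix is scaled row-wise by these weights, then passes
through a Kim-style convolutional classifier: per-window-size sigmoid
convolutions (windows {2, 3, 5, 7}, 48 filters each), max-over-time
pooling, and a dense softmax over the four categories.  Training
minimizes cross-entropy + (λ/2)‖W‖² with mini-batch Adam and returns the
parameters at the validation-accuracy peak.  Three baselines share the
code path: the same CNN with all weights forced to 1 (random or word2vec
initialization) and an averaged-embedding softmax model.

Since real triage corpora are access-restricted and the LIWC dictionary
is proprietary, the package includes a synthetic generator
(`planted_signal_spec()`) producing lexica and labeled corpora with known
class-conditional structure, plus CLPsych-style metrics (Non-green F1,
Flagged F1/Acc, Urgent F1/Acc, All F1/Acc).  See the methods vignette
(`vignettes/triage-weighting-cnn.Rmd`) for the full model description and
design rationale.

## Worked example

```r
library(liwcnn)

spec    <- planted_signal_spec(seed = 42)       # 1600 posts, planted class 1
lexicon <- generate_lexicon(spec, seed = 42)
corpus  <- generate_corpus(spec, lexicon, seed = 42)
parts   <- split_train_val(corpus, fraction = 1 - 200 / nrow(corpus), seed = 42)

tc   <- preprocess_corpus(parts$train, n = 100)
freq <- compute_class_frequencies(tc, lexicon)
disc <- discriminability(freq, k = 8)
round(disc$sd, 3)
#> synclass01_c synclass02_c synclass03_c synclass04_c synclass05_c synclass06_c
#>        0.719        0.062        0.094        0.037        0.031        0.062
#> synclass07_c synclass08_c
#>        0.066        0.072
```

The planted class (`synclass01_c`, emission rates 0.08/0.05/0.02/0.005
for crisis/red/amber/green) dominates the discriminability ranking; the
seven uniform classes show only sampling noise.  Training the attention
CNN and scoring the 200 held-out posts:

```r
model <- train_liwcnn(parts$train, lexicon, demo_train_config(seed = 42))
test  <- preprocess_corpus(parts$val, n = 100, polarity_map = model$polarity_map)
evaluate_triage(test$labels, predict(model, test)$labels)
#> Triage evaluation
#>   Non-green F1 0.9599 | Flagged F1 1.0000 Acc 1.0000 | Urgent F1 0.9709 Acc 0.9700 | All F1 0.9699 Acc 0.9700
#>   Confusion (gold rows x pred cols):
#>         pred
#> gold     green amber red crisis
#>   green     50     0   0      0
#>   amber      0    44   6      0
#>   red        0     0  50      0
#>   crisis     0     0   0     50
```

97% four-way accuracy on held-out posts: the model recovers the planted
lexical signal and the emoji polarity structure.  The only confusions are
amber posts read as red — the hardest boundary, since both categories
differ mainly in the planted class's emission rate.

A command-line launcher wrapping the same pipeline
(`simulate` / `weights` / `train` / `evaluate`) ships in
[`inst/cli/liwcnn`](inst/cli/liwcnn).

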