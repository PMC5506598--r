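# nerlstm

Clinical texts are dense with typed entity mentions — problems, tests,
treatments, and protected health information (PHI) such as dates and record
numbers — and locating them is the first step of most clinical NLP
pipelines. `nerlstm` treats the task as sequence labeling and implements a
bidirectional peephole-LSTM encoder with a linear-chain conditional random
field (CRF) inference layer, entirely in R with hand-derived
backpropagation, so every layer is inspectable and unit-testable.

## The model

A sentence `s = w1 … wn` is mapped to vectors in three layers:

1. **Input layer.** Each word is the concatenation of a token-level
   embedding (looked up in a table loadable from word2vec text format and
   fine-tuned during training) and an optional character-level vector that
   captures morphology: either the final forward/backward states of a
   character bi-LSTM, or max-pooled responses of a character CNN.
2. **Encoder.** A bidirectional LSTM with peephole gates

   ```
   i_t = σ(W_xi x_t + W_hi h_{t-1} + w_ci ⊙ c_{t-1} + b_i)
   f_t = σ(W_xf x_t + W_hf h_{t-1} + w_cf ⊙ c_{t-1} + b_f)
   c_t = f_t ⊙ c_{t-1} + i_t ⊙ tanh(W_xc x_t + W_hc h_{t-1} + b_c)
   o_t = σ(W_xo x_t + W_ho h_{t-1} + w_co ⊙ c_t + b_o)
   h_t = o_t ⊙ tanh(c_t)
   ```

   run in both directions; the context vector at position t is
   `h_t = [h_ft ; h_bt]`.
3. **Inference layer.** A linear-chain CRF whose score for a label sequence
   `y` is `Σ_t θ_{y_{t-1} y_t}ᵀ h_t` — one full weight vector per ordered
   label transition, dotted with the encoder output (a distinctive
   parameterization; the usual emission + scalar-transition factorization is
   available as an option). The likelihood is globally normalized by the
   forward algorithm in log space; decoding is exact Viterbi. Dropping the
   transition structure reduces inference to a per-token softmax
   (`softmax_decode()`), kept as the non-structured baseline.

Entities are encoded as BIOES tags (`B`/`I`/`E` for multi-token mentions,
`S` for single-token, `O` outside); a deterministic repair policy turns any
invalid model output back into well-formed character-span mentions.
Training is plain per-sentence SGD with global-norm gradient clipping and
inverted dropout. Evaluation reports micro-averaged precision/recall/F1
under five matching criteria (exact, inexact, span, type, token).

Because the clinical corpora this family of models is benchmarked on are
access-restricted, the package ships a seeded generator of clinical-style
annotated corpora (`corpus_spec()` / `generate_corpus()`) whose entity
surfaces carry controllable morphology cues — suffixed disease/drug-like
words, digit-patterned dates and IDs — so the benefit of character-level
representations on out-of-vocabulary entities is measurable end to end
without any external data.

## Worked example

```r
library(nerlstm)

corpus <- generate_corpus(corpus_spec(n_documents = 10,
                                      sentences_per_doc = c(5, 5), seed = 3))
train <- corpus_tokens(corpus$train)     # tokenized, BIOES-tagged tibble

cfg <- ner_config(token_dim = 10, token_lstm_size = 10, dropout = 0,
                  learning_rate = 0.05, epochs = 40, seed = 9)
model <- ner_train(train, mode = "token", config = cfg)

pred <- predict(model, setNames(corpus$test$docs$text, corpus$test$docs$doc_id))
head(pred, 3)
#> # A tibble: 3 × 5
#>   doc_id   type  start   end text
#>   <chr>    <chr> <int> <int> <chr>
#> 1 test-001 date     56    64 12/22/73
#> 2 test-001 date    171   178 8/20/55
#> 3 test-001 test    258   262 mild

evaluate_corpus(corpus$test$mentions, pred,
                criteria = c("exact", "inexact", "span"), per_type = FALSE)
#> # A tibble: 3 × 8
#>   criterion type     tp    fp    fn precision recall    f1
#>   <chr>     <chr> <int> <int> <int>     <dbl>  <dbl> <dbl>
#> 1 exact     <all>     6     9    19     0.4     0.24   0.3
#> 2 inexact   <all>     8     7    17     0.533   0.32   0.4
#> 3 span      <all>    12     3    13     0.8     0.48   0.6
```

The mention tibble gives character spans into the raw documents (0-based,
half-open) with the surface text. The evaluation rows show how the
criteria relax: `exact` requires identical boundaries and type, `inexact`
accepts overlap with the right type, `span` accepts any overlap — so
true-positive counts can only grow down the table. A token-only model on a
test split whose entity words were never seen in training (here the dates
and digit IDs are recognizable from context tokens like `/`, the suffixed
words are not) is exactly the regime where the `char-lstm` / `char-cnn` /
`both` input modes pay off; `tidy(model)` returns the per-epoch loss trace
and `autoplot(model)` plots it.

A thin command-line interface wraps the same functions:

```sh
Rscript inst/cli/nertagger.R generate --out corpus --seed 5 --n-documents 20
Rscript inst/cli/nertagger.R train --conll corpus/train/corpus.conll \
        --model model.rds --mode char-lstm --epochs 30 --seed 5
Rscript inst/cli/nertagger.R tag --model model.rds \
        --text corpus/test/test-001.txt --out pred.ann
Rscript inst/cli/nertagger.R evaluate --gold corpus/test/test-001.ann \
        --pred pred.ann --text corpus/test/test-001.txt
```

The model archive written by `save_model()` / the CLI is a single versioned
RDS file containing all parameters, both embedding tables, the label set
and the config snapshot; `load_model()` restores it to bit-identical
predictions.

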