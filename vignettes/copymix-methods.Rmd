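---
title: "Models and design choices in copymix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in copymix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(copymix)
```

`copymix` codes DNA one symbol at a time: an ensemble of predictors emits a
probability distribution over `{A,C,G,T}` at every position, the
distributions are blended, and the blend drives an arithmetic coder. The
same pipeline run without emitting a payload yields per-position information
content, bit rates and Normalized Compression. This vignette explains the
models, the tunable parameters, and the places where the design was
genuinely open and a choice had to be made.

## Finite-context models

An order-*k* FCM holds, for each context of *k* past symbols, four
occurrence counters, and predicts

$$P(s \mid ctx) = \frac{n_s + \alpha}{\sum_{s'} n_{s'} + 4\alpha}.$$

Parameters and defaults:

* `k` — context order. Low orders learn fast and saturate high; high orders
  are sharp once their contexts have been seen. Presets combine several.
* `alpha` — estimator smoothing, default 1 for `k < 10` and 1/16 for
  `k ≥ 10`. High orders see each context rarely, so a strong prior toward
  uniform would dominate the estimate; 1/16 lets a handful of observations
  produce a confident prediction. This is the standard choice in the FCM
  compression literature, which defines the estimator family but no single
  value.
* counters are 8-bit and all four counters of a context are halved
  (rounding down) whenever one reaches 255. Halving doubles as a forgetting
  mechanism: old statistics fade with a half-life of one saturation cycle.
* tables are direct-indexed while `4^k` fits in the table budget
  (`max_table_bits`, default 24, i.e. 16.7M contexts ≈ 64 MB of counters);
  beyond that, contexts are placed by multiplicative hashing (fixed odd
  constant, power-of-two table) and collisions silently share a row. This
  keeps memory bounded and is deterministic with no seed, which the
  encoder/decoder symmetry requires.

With `inverted_repeats = TRUE` each observed symbol additionally updates the
same table with the reverse-complement event: after observing `x[i]`, the
context `rc(x[i-k+1..i])` is credited with symbol `comp(x[i-k])`. Prediction
still reads only the forward context; the folded updates simply make the
table symmetric under strand reversal. This single-table folding is how the
FCM-compressor lineage treats inverted repeats, and it is what makes a
reverse-complemented copy of previously seen sequence cheap (the test suite
checks a >2x gain on such a copy).

## Substitution-tolerant context models

An STCM predicts with the FCM estimator but on its own context register. Its
update rule needs bookkeeping the literature leaves open; the rule here is:

* if the observed symbol equals the model's current argmax (ties broken
  toward the lowest symbol index), the mismatch counter decays by one
  (floor 0) and the true symbol enters the context;
* otherwise the counter increments and the *argmax* symbol enters the
  context — the model pretends the mutation did not happen;
* when the counter exceeds `t`, the register is reset to the true history
  and the counter to zero.

With `t = 0` any mismatch resets immediately and the STCM degenerates to an
FCM trajectory. In the shipped presets each STCM shares its count table with
the same-order FCM: the pair costs one table, and the STCM differs only in
the context it conditions on. (Whether to share was an open choice; sharing
bounds memory and measured slightly better on the mutated-copy fixtures.) A
standalone STCM owns a private table which it updates with the symbol it
propagated.

## Repeat models

A repeat model bets the next symbol equals `x[pointer]`, assigning

$$P(\mathrm{hit}) = \frac{N_h + 1}{N_h + N_m + 2}, \qquad
  P(s \neq \mathrm{hit}) = \frac{1 - P(\mathrm{hit})}{3}.$$

Both forms are precomputed for all `N_h + N_m ≤ 200` (the model rarely
survives longer than that) and evaluated analytically — same closed form,
bit-identical — beyond the bound.

Recent performance is tracked by the low-pass filter `Y ← X + βY`. The
instantaneous performance `X` is not defined by the stop rule alone; here
`X = 1` on a miss and `0` on a hit, so `Y` accumulates recent failure, a run
of hits decays it geometrically, and the stop condition `Y > L` reads "the
model has been wrong too often lately". With the defaults `β = 0.9`,
`L = 7`, a fresh model dies after exactly 12 consecutive misses
(`Y_n = (1-0.9^n)/0.1 > 7` first at `n = 12`), which the tests assert
analytically. Larger `β` or `L` tolerate noisier repeats; the defaults suit
substitution rates around 1% and are stored per container.

Start positions come from a cache-table keyed by the exact 2*k*-bit *k*-mer,
holding the most recent `c` positions each (FIFO eviction, worst case
`4^k·c` entries — why `k ≤ 15` is a hard limit and 12–14 the practical
range). When the current *k*-mer has cached occurrences and a model slot is
free, one occurrence is chosen by `next_lcg() mod ring_size` using the
classic Numerical-Recipes LCG (multiplier 1664525, increment 1013904223,
modulus 2^32) with a seed stored in the container — pseudo-random spread
over candidates, bit-reproducible on both sides. A stopped model frees its
slot immediately and the slot may restart at the next *k*-mer hit. At most
`n_models` models run at once; a start is attempted only when a slot is
free. These scheduling details (slot reuse, one start attempt per position)
were unspecified design space; the choices here are the simplest
deterministic ones.

## Mixing

The blend is `P(s) = Σ_m w_m P_m(s)`, renormalized, followed by a
probability floor of `2^-16` per symbol: a finite-precision arithmetic coder
cannot encode a zero-probability symbol, and exception placeholders can make
any symbol occur anywhere. Weights update as

$$w_m \leftarrow w_m^{\gamma_m} \, P_m(x_i),$$

normalized, floored at `weight_floor = 1e-6`, renormalized. `γ = 1` is exact
Bayesian mixture updating; `γ < 1` (default 0.95 everywhere) flattens old
evidence so the mixture can switch to whichever model currently predicts
well within tens of symbols. The floor prevents a model that was useless for
a megabase from being locked out forever. The extra normalize-floor-
renormalize order (rather than flooring raw products) avoids underflow of
the running weights; the semantics are the same.

An inactive repeat-model slot still occupies its mixture position and emits
the uniform distribution. This was an open bookkeeping question: removing
slots from the mixture would force a weight-vector resize at every
start/stop on both sides. Letting idle slots predict uniform keeps the
weight vector fixed-size, costs them weight exactly in proportion to their
uselessness, and lets a restarted model inherit whatever weight its slot
retained.

The mixer is an interface: the engine consumes any per-model distribution
set, so a learned (e.g. neural) mixer can replace soft-blending without
touching the coder. Only soft-blending ships.

## Coding and container

The coder is a standard 32-bit range coder with carry-less renormalization.
Blended probabilities are quantized to 16-bit cumulative frequencies with a
deterministic rule (`f_s = floor(p_s · 65532) + 1` for the first three
symbols, remainder to the last) so every symbol keeps a nonzero range and
both sides compute identical integers from identical doubles. Measured
overhead versus the information content `Σ -log2 p` is below 0.1% plus a
constant tail (the tests bound it at 0.1% + 64 bytes).

Headers (with FASTQ `+` lines), qualities, exception characters, the
lowercase run-length mask and the line-layout metadata are separate channels
coded by a generic adaptive byte model (order 3 for headers, 2 for
qualities, 1 for the rest) through the same coder. The container stores
magic, version, format, a CRC-32 of the original bytes, the fully resolved
profile as JSON (so decompression needs no external knowledge, and presets
can change without breaking old archives), and length-prefixed channels.
Out-of-alphabet characters are replaced by placeholder index 0 in the model
stream and restored from the exception channel; lowercase bases are
uppercased for modelling and restored from the case mask. Only `\n` line
endings are supported — a byte-exact reconstruction contract has no room for
ambiguity, so files containing `\r` fail fast.

## Analysis outputs

Normalized Compression is `NC(x) = C(x) / (|x| · log2 |Σ|)` with `C(x)` the
*sequence-channel* payload in bits. Headers, qualities and container framing
are excluded deliberately: NC is a property of the symbolic sequence, and
framing would add noise that depends on description length, not sequence
structure. The bit-information profile reports `-log2 P(x_i | x_{<i})` per
position from the identical pipeline in estimation mode; totals reconcile
with coded payload sizes to within the coder's constant overhead, and the
profile is emitted as plottable TSV.

## The synthetic generator, and what the tests do and do not show

All calibration inputs are generated: uniform i.i.d. DNA (entropy
2 bits/base), order-*k* Markov chains with Dirichlet(2) rows and an
analytically computed entropy rate, tandem repeats, dispersed repeats, and
mutated copies with a known substitution ledger. Generation uses one seed
for structure and a derived stream (`seed + 777007`) for mutations, so
changing the substitution rate never changes the underlying sequence —
differential tests depend on that. The calibration sizes are 1e6 symbols for
the entropy and incompressibility checks (sampling error well below the
0.02–0.05 bit tolerances), 2e5 for the repeat fixtures, and 1,000 fuzzed
files for the losslessness sweep.

These fixtures validate the estimators, the mixing and the coder against
known ground truth. They do *not* emulate real genomes: no CpG structure, no
repeat families with internal indels (the models here handle substitutions,
not gaps), no chromosome-scale heterogeneity. Passing them shows the
machinery is correct and calibrated, not that compression ratios on a
particular genome will match any published figure.

## Known limitations

* Repeat pointers follow the forward strand only; inverted-repeat handling
  lives in the FCM tables.
* Indels break copy-model alignment; the STCM tolerates substitutions only.
* `k > 15` repeat anchors would need a hash-table position store and are
  rejected.
* Single-threaded by design; `--threads` is reserved.
* FASTQ parsing assumes the conventional 4-line record form.
* No random access into containers: decoding is sequential from the start.
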