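---
title: "Decision depth, trace memory, and the learning cost of representing sequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decision depth, trace memory, and the learning cost of representing sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqlearn)
```

## The question

An organism that decides based only on the most recent stimulus has to learn
the right response to at most $n$ situations, where $n$ is the number of
stimuli it can perceive. One that conditions its decisions on the last
$\ell$ stimuli — its *decision depth* — can in principle respond to richer,
order-dependent information, but faces up to $N(\ell) = n^\ell$ distinct
situations, each of which must be learned by trial and error. `seqlearn`
implements two complementary engines for studying this trade-off:

1. a **closed-form cost–benefit model** of decision depth, giving the
   expected number of productive decisions over a lifetime as a function of
   $\ell$, and
2. an **agent-based go/no-go simulator** in which associative learners
   equipped with different sequence representations — a decaying stimulus
   trace, a fixed-depth ordered window, or a flexible set of subsequences —
   are trained by error-correction learning in synthetic template-sequence
   worlds.

## The analytic model

A decision is *productive* when it is the option with the highest utility.
Write $u(\ell, t)$ for the probability that the decision at time $t$ is
productive. Lifetime utility over $T$ learning experiences is

$$U(\ell, T) = \sum_{t=0}^{T-1} u(\ell, t).$$

Two quantities govern $u$. First, $f(\ell) = 1 - r^\ell$ is the fraction of
length-$\ell$ histories that contain enough information for a productive
decision; the rate $r \in (0,1)$ controls how quickly looking deeper into
the past pays off. Second, learning a single productive decision takes
$\tau$ experiences, and there are $N(\ell) = n^\ell$ situations to learn, so
starting from no innate knowledge ($u(\ell,0)=0$) the per-step probability
grows by

$$u(\ell, t+1) = u(\ell, t) + \frac{1}{\tau N(\ell)}\,
  \bigl[f(\ell) - u(\ell, t)\bigr],$$

whose solution is $u(\ell,t) = f(\ell)\bigl[1 - (1 - 1/(\tau
N(\ell)))^t\bigr]$ and hence

$$U(\ell,T) = f(\ell)\left[T - \tau N(\ell)\left(1 -
  \Bigl(1 - \frac{1}{\tau N(\ell)}\Bigr)^{T}\right)\right].$$

Any constant scaling of $N(\ell)$ (not all $n^\ell$ sequences are
realizable) can be folded into $\tau$, which is why `tau` is real-valued.

### Parameters

| symbol | argument | meaning | default in examples |
|---|---|---|---|
| $n$ | `n` | perceivable stimuli (count, $\ge 2$) | varies |
| $r$ | `r` | information-distribution rate, $(0,1)$ | 0.5 |
| $\tau$ | `tau` | experiences per learned decision | 10 |
| $T$ | `lifespan` | lifetime in learning experiences | $10^4$ |
| $\ell$ | `depth` | decision depth (integer $\ge 1$) | 1–4 |

### Numerical choices

The term $(1 - 1/(\tau N))^T$ is evaluated as
$\exp(T \log(1 - 1/(\tau N)))$ via `log1p()`/`expm1()`: for large alphabets
$\tau N$ can exceed $10^9$ while $T$ reaches $10^6$, where naive powering
loses precision. `num_sequences()` additionally carries the exact decimal
expansion of $n^\ell$ (computed by integer long multiplication) so counts
beyond $2^{53}$ remain exact. `productive_prob_recurrence()` iterates the
recurrence literally and is used throughout the tests as a brute-force
oracle for the closed form; `lifetime_utility()` is likewise checked against
the explicit per-step sum. Ties in `optimal_depth()` go to the smaller
depth: at equal utility the cheaper representation wins.

```{r analytic}
p <- analytic_params(n = 12, r = 0.5, tau = 10, lifespan = 10000)
utility_surface(p)
depth_boundary_n(r = 0.5, tau = 10, lifespan = 10000)
```

With $T = 10^4$, $r = 0.5$ and $\tau = 10$, scanning alphabet sizes shows
depth 2 beating depth 1 only for $n < 20$ — already a 20-stimulus world
makes the combinatorial cost prohibitive.

## The simulated worlds

An environment is an alphabet of *informative* and *noise* stimuli plus a
set of length-4 *template sequences*; each template fixes some positions to
concrete informative stimuli, leaves the rest as noise wildcards, and is
labelled rewarding or not. Exactly half of the templates are rewarding —
this invariant is enforced by construction and checked by the test suite.
Sampling draws a template uniformly and fills each wildcard uniformly (with
replacement) from the environment's wildcard pool. Fractional design
parameters (position distributions, depth fractions, the sequential
fraction $p$) are converted to integer template counts by deterministic
largest-remainder rounding, which keeps the half-rewarding invariant exact.

Three families are provided:

* `build_positional_env()` — all information in one stimulus identity,
  placed at the last position, uniformly over positions, or at the first
  position. Two informative identities (one rewarding, one not) among 66
  stimuli, 32 templates.
* `build_graded_depth_env()` — each template's informative position sits at
  recency $k$ with template proportions $(1/2, 1/4, 1/8, 1/8)$ for
  $k = 1..4$: information grows with depth at rate $0.5$ and stops at
  depth 4. Each of the 16 templates carries its own informative identity, so
  the number of stimulus–response situations a depth-$\ell$ learner must
  master scales with the template count times the noise alphabet to the
  power $\ell - 1$ — the simulated analogue of $n^\ell$. Used with 20- and
  500-stimulus alphabets.
* `build_order_env()` — a fraction $p$ of the informative templates carry
  the ordered bigram $(A,B)$ (rewarding) or $(B,A)$ (non-rewarding) at each
  offset where it fits; the rest carry one concrete single identity.
  Whenever bigrams are present, A and B also occur *alone* (in fixed
  concrete noise contexts, A rewarding and B not, across the last three
  positions) and *intermixed* (the wildcard pool includes A and B), so that
  no single stimulus, position, or bare presence of A or B reveals the
  bigram's order.

### Why the order worlds need the intermixing

In discrete time with unit stimulus durations, a decaying trace assigns the
bigram's two symbols intensities in the exact ratio $\theta$ (for $A,B$) or
$1/\theta$ (for $B,A$). Without further structure this ratio is a perfectly
reliable order cue, and a linear associative learner provably separates the
two orders (choose $w_B > 0$ and $-2w_B < w_A < -\theta w_B$ at
$\theta = 0.5$). Real traces do not enjoy such clean ratios: stimulus
durations and decay vary, blurring intensity as an order code. The package
models that blur structurally rather than by simulating durations: A and B
appear alone with full intensity in both reward roles of the
order-discrimination problem's *context* (A-alone rewarding, B-alone not)
and as occasional wildcard fills, which makes the ratio cue unreliable and
punishes the weight configuration that reads it. With this design the trace
learner stays near the 0.5 base rate when all information is order-borne,
while window-based representations master the world — the qualitative
pattern the simulator is built to exhibit. The A/B-alone context-template
count (default 20 against 48 bigram templates) was fixed during design
calibration; fewer context templates leave the trace a partially working
ratio cue.

## The agent

Each stimulus sequence is perceived as a set of *perception elements*
$(K, x)$ — a subsequence and an intensity:

```{r representations}
s <- c("D", "C", "B", "A")
represent_trace(s, theta = 0.5)
represent_depth(s, 2)
represent_flexible(s, 2)
```

Order is carried by the key: `"A B"` and `"B A"` are different
subsequences. This is the entire mechanism by which window-based strategies
are order-sensitive and the trace is not (its keys are single stimuli;
order survives only in intensity). "All subsequences" for the flexible
strategy means all *contiguous* ones: $\ell(\ell+1)/2$ elements for a
window of $\ell$ distinct stimuli. Repeated stimuli merge by summing
intensities (trace accumulation); `merge = "recent"` keeps only the newest
trace instead.

The memory maps (subsequence, behavior) pairs to associative strengths,
with unseen pairs reading exactly 0 (no innate knowledge). The value of a
behavior is the intensity-weighted sum of its strengths over the percept.
During learning the agent goes with softmax probability
$\sigma(\beta(v_{go} - v_{nogo}))$ with sharpness $\beta = 1$, earns +5 for
responding to a rewarding sequence, −4 for responding to a non-rewarding
one, and 0 for withholding, and updates the chosen behavior's strengths by
a normalized delta rule with prediction error $\delta$:

$$w(K, b) \mathrel{+}= \alpha\, x\, \delta \Big/ \Bigl(\sum_j x_j\Bigr)^2.$$

One experience therefore moves the percept's value toward the reinforcement
by the fraction $\alpha \sum x^2 / (\sum x)^2$: a single-element percept
(any Depth-$\ell$) moves by the full $\alpha$, the four-element trace by
$\approx 0.38\,\alpha$, and the ten-element flexible percept by
$0.1\,\alpha$. Spreading perception over more elements is thus paid for in
learning speed — the representation-cost mechanism at the heart of the
strategy comparison. (Normalizing by $\sum x^2$ instead would equalize the
per-experience value step across strategies and erase exactly the cost the
comparison is about.) Because withholding earns 0 and no-go values start at
0, no-go strengths never leave 0; all learning lives on the go side.

### Measuring performance

Every `measure_every = 100` steps the simulation freezes and the agent is
scored on a fixed test set (10 instantiations per template, drawn once per
run) without any weight change. The default score is the *expected*
fraction correct: each item contributes the softmax probability of the
correct response. A naive agent scores exactly 0.5 on any half-rewarding
test set, and the score reflects graded knowledge — an association must
approach its reinforcement value before an item counts as essentially
solved. A greedy readout (argmax, ties to no-go) is also provided; note
that under go/no-go a greedy sign readout counts a key as solved after a
single reinforced exposure, which erases the $\tau$-timescale of learning
and with it the depth-1 versus depth-2 separation the graded-depth worlds
are designed to exhibit.

### Calibration of the learning rate

The analytic model's $\tau \approx 10$ means a discrimination costs about
ten experiences. Under the expected-accuracy readout, a rewarding
single-element discrimination reaches expected accuracy
$\sigma\!\bigl(5(1 - (1-\alpha)^j)\bigr)$ after $j$ reinforced exposures;
$\alpha = 0.05$ puts ten exposures at $\approx 0.88$ — learned, on the
$\tau = 10$ timescale. This is the package default. With it, the
500-stimulus graded-depth world shows the depth-1 learner plateauing near
75% correct by trial 5,000 while the depth-2 learner needs over 100,000
trials (more than 20 times longer) to match it — the quantities the
acceptance script recomputes.

## Running experiments

```{r running, eval = FALSE}
env <- build_graded_depth_env(500)
cmp <- compare_strategies(env, lapply(1:4, strategy_depth),
                          steps = 300000, replicates = 20, seed = 1)
plot(cmp, level = 0.75)
curve_milestones(cmp, at = c(5000, 80000))
```

Each replicate derives an environment-stream seed, a test-set seed and an
agent seed from the master seed; the first two do not depend on the
strategy, so in `compare_strategies()` every strategy faces identical
stimulus streams and test sets (paired comparisons, common random
numbers). Runs are bit-for-bit reproducible given the seed. The inner loop
is compiled (C++); a pure-R reference engine (`engine = "R"`) implements
the identical loop from the exported module functions and the test suite
asserts the two agree to numerical precision. A divergence guard aborts if
any strength's magnitude exceeds $10^6$, which signals a mis-set
$\alpha$/$\beta$ rather than a valid result.

`figure_preset()` bundles the canonical settings: the 20- and 500-stimulus
graded-depth worlds (Depth-1..4), the three positional worlds (Trace and
Depth-1..4, 10,000 steps), and the order worlds at
$p \in \{0, .25, .5, .75, 1\}$ (Trace, Depth-4, Flexible-4, 300,000
steps). Step counts are package choices: long enough that fast strategies
sit at their plateaus and slow ones are clearly separated. The test suite
exercises these designs at 6–20 replicates and up to $3\times 10^5$ steps;
the milestone assertions (the 75%-at-5,000 level, the $\ge 16\times$
depth-2 delay, the strategy orderings in each world) are computed at those
sizes.

## What the generator does and does not emulate

The synthetic worlds reproduce the structural features the theory is
about: where in time information sits, how much of it is order-borne, and
how the number of situations scales with representation depth. They do not
emulate naturalistic stimulus statistics — draws are uniform (no Zipfian
frequencies), stimuli are featureless tokens (no perceptual similarity or
generalization), sequences have fixed length 4 and unit durations, and
reinforcement is deterministic given the template. Passing tests therefore
show that the implemented mechanisms produce the claimed cost orderings
under these controlled conditions, not that real organisms' learning curves
would match quantitatively.

## Limitations and non-goals

* No evolutionary dynamics: strategies are compared by learning curves and
  lifetime utility, not selection or inheritance.
* No memory-storage or processing-time costs; only learning costs are
  modelled.
* No recursive chunking or hierarchical re-encoding of sequences.
* No statistical hypothesis tests across strategy curves; comparisons are
  reported as curves and milestones.
* The trace's failure on order-borne information is induced structurally
  (context templates and intermixing) rather than by simulating variable
  stimulus durations; worlds without that structure let a discrete-time
  trace read order from exact intensity ratios.
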