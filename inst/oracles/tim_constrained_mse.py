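"""Independent constrained-MSE solver for the KL-budgeted response problem.

Reads JSON {"q": [...], "n": int, "C": float} (1-based stimulus index) from
argv[1], minimizes the expected squared error sum_k p_k (n - k)^2 over the
probability simplex subject to KL(p || q) <= C, and prints the solution pmf
as JSON.

Route: Lagrangian duality. The problem is convex with a strictly feasible
point (p = q), so strong duality holds and the dual function

    g(lam) = min_p [ c'p + lam (KL(p||q) - C) ]
           = -lam * logsumexp(log q - c / lam) - lam * C        (lam > 0)

is concave in the multiplier lam. g is maximized by high-precision scalar
optimization (grid bracket + golden/Brent refinement via scipy), and the
primal solution is recovered from the inner minimizer. This determines the
multiplier through dual ascent rather than through root-finding on the KL
constraint, so it serves as an independent check of the package's solver.
Used only as a numerical oracle in the test suite.
"""
import json
import sys

import numpy as np
from scipy.optimize import minimize_scalar
from scipy.special import logsumexp

spec = json.load(open(sys.argv[1]))
q = np.asarray(spec["q"], dtype=float)
n = int(spec["n"])
C = float(spec["C"])
m = q.size
k = np.arange(1, m + 1, dtype=float)
c = (k - n) ** 2
logq = np.log(q)


def neg_dual(loglam):
    lam = np.exp(loglam)
    return -(-lam * logsumexp(logq - c / lam) - lam * C)


# bracket the maximizer on a wide log-spaced grid, then refine
grid = np.linspace(np.log(1e-9), np.log(1e12), 2001)
vals = np.array([neg_dual(x) for x in grid])
i = int(np.argmin(vals))
lo = grid[max(i - 1, 0)]
hi = grid[min(i + 1, grid.size - 1)]
res = minimize_scalar(neg_dual, bounds=(lo, hi), method="bounded",
                      options={"xatol": 1e-14, "maxiter": 10000})
lam = float(np.exp(res.x))
logp = logq - c / lam
logp -= logsumexp(logp)
p = np.exp(logp)
p /= p.sum()
kl = float(np.sum(p[p > 0] * (np.log(p[p > 0]) - logq[p > 0])))
json.dump({"pmf": p.tolist(), "lam": lam, "kl": kl}, sys.stdout)
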