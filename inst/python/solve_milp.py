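"""Solve a 0/1 integer linear program with scipy's HiGHS MILP interface.

Input: JSON file with fields
  nvar      : number of binary variables
  obj       : objective coefficients (minimized)
  A         : {"i": [...], "j": [...], "x": [...]} 1-based triplets
  row_lb    : per-row lower bounds (-1e30 for none)
  row_ub    : per-row upper bounds ( 1e30 for none)
  time_limit: seconds (optional)
Output: JSON file with fields status, x, objective, gap.
"""
import json
import sys

import numpy as np
from scipy import sparse
from scipy.optimize import Bounds, LinearConstraint, milp


def main(inp, out):
    with open(inp) as fh:
        prob = json.load(fh)
    n = int(prob["nvar"])
    obj = np.asarray(prob["obj"], dtype=float)
    A = sparse.csr_matrix(
        (np.asarray(prob["A"]["x"], dtype=float),
         (np.asarray(prob["A"]["i"], dtype=int) - 1,
          np.asarray(prob["A"]["j"], dtype=int) - 1)),
        shape=(len(prob["row_lb"]), n))
    lb = np.asarray(prob["row_lb"], dtype=float)
    ub = np.asarray(prob["row_ub"], dtype=float)
    lb[lb <= -1e29] = -np.inf
    ub[ub >= 1e29] = np.inf
    options = {"mip_rel_gap": 1e-9}
    if prob.get("time_limit"):
        options["time_limit"] = float(prob["time_limit"])
    res = milp(c=obj, integrality=np.ones(n),
               bounds=Bounds(np.zeros(n), np.ones(n)),
               constraints=LinearConstraint(A, lb, ub),
               options=options)
    status = {0: "optimal", 1: "iteration_limit", 2: "infeasible",
              3: "unbounded", 4: "other"}.get(res.status, "other")
    if status == "iteration_limit" and res.x is not None:
        status = "time_limit"
    payload = {"status": status,
               "objective": None if res.x is None else float(res.fun),
               "gap": None if res.mip_gap is None else float(res.mip_gap),
               "x": None if res.x is None else [int(round(v)) for v in res.x]}
    with open(out, "w") as fh:
        json.dump(payload, fh)


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
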