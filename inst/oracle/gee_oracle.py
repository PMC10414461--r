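"""Independent GEE reference fit used only as a cross-check oracle in tests.

Reads a panel CSV, fits a Gaussian GEE with exchangeable working
correlation via statsmodels, and writes the coefficient vector, robust
(sandwich) standard errors, exchangeable correlation estimate and scale as
JSON.

Usage: python gee_oracle.py <panel.csv> <outcome> <cluster> <cov1,cov2,...> <out.json>
"""
import json
import sys

import numpy as np
import pandas as pd
import statsmodels.api as sm


def main(argv):
    path, outcome, cluster, covs, out = argv[1:6]
    covs = covs.split(",")
    df = pd.read_csv(path)
    endog = df[outcome].to_numpy(float)
    exog = sm.add_constant(df[covs].to_numpy(float))
    model = sm.GEE(endog, exog, groups=df[cluster],
                   family=sm.families.Gaussian(),
                   cov_struct=sm.cov_struct.Exchangeable())
    res = model.fit(maxiter=200, ctol=1e-12)
    payload = {
        "beta": res.params.tolist(),
        "se": res.bse.tolist(),
        "alpha": float(model.cov_struct.dep_params),
        "scale": float(res.scale),
        "terms": ["(Intercept)"] + covs,
    }
    with open(out, "w") as fh:
        json.dump(payload, fh)


if __name__ == "__main__":
    main(sys.argv)
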