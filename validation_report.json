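{
  "pass": true,
  "inversion": [
    {
      "pair": "1/q <-> 1",
      "smooth": true,
      "err_durbin": 0,
      "err_zakian": 0
    },
    {
      "pair": "1/q^2 <-> t",
      "smooth": true,
      "err_durbin": 5.83691167634903e-05,
      "err_zakian": 6.30604577445126e-08
    },
    {
      "pair": "1/((q+1)(q+2)) <-> exp(-t)-exp(-2t)",
      "smooth": true,
      "err_durbin": 4.05021356730817e-09,
      "err_zakian": 2.04474998599657e-08
    },
    {
      "pair": "1/(q+1) <-> exp(-t)",
      "smooth": true,
      "err_durbin": 6.14373853438654e-06,
      "err_zakian": 4.43083802703637e-08
    },
    {
      "pair": "1/(q+1)^2 <-> t exp(-t)",
      "smooth": true,
      "err_durbin": 2.26927011903744e-08,
      "err_zakian": 2.95024312757519e-08
    },
    {
      "pair": "1/(q+0.5) <-> exp(-t/2)",
      "smooth": true,
      "err_durbin": 6.09031916187774e-06,
      "err_zakian": 2.63057036153924e-08
    },
    {
      "pair": "1/(q^2+1) <-> sin(t)",
      "smooth": false,
      "err_durbin": 6.13867348586705e-06,
      "err_zakian": 5.76569906263202e-08
    },
    {
      "pair": "1/q^1.5 <-> t^0.5/Gamma(1.5)",
      "smooth": false,
      "err_durbin": 2.11350798375864e-05,
      "err_zakian": 0.00138655432623214
    },
    {
      "pair": "exp(-sqrt(q))/q <-> erfc(1/(2 sqrt(t)))",
      "smooth": false,
      "err_durbin": 5.02935189428122e-06,
      "err_zakian": 0.000528711707520446
    }
  ],
  "cross": [
    {
      "alpha": 0.8,
      "phi": 0.02,
      "R": 0.5,
      "max_abs_diff": 0.000215181659619645
    }
  ]
}
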