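{"sig1_like":[0.00108695652173913,0.00108695652173913,0.00108695652173913,0.00108695652173913,0.00108695652173913,0.00108695652173913,0.00108695652173913,0.00108695652173913,0.00108695652173913,0.00108695652173913,0.00108695652173913,0.00108695652173913,0.00108695652173913,0.00108695652173913,0.00108695652173913,0.00108695652173913,0.00108695652173913,0.00108695652173913,0.00108695652173913,0.00108695652173913,0.00108695652173913,0.00108695652173913,0.00108695652173913,0.00108695652173913,0.00108695652173913,0.00108695652173913,0.00108695652173913,0.00108695652173913,0.00108695652173913,0.00108695652173913,0.00108695652173913,0.00108695652173913,0.00108695652173913,0.00108695652173913,0.225,0.00108695652173913,0.00108695652173913,0.00108695652173913,0.225,0.00108695652173913,0.00108695652173913,0.00108695652173913,0.225,0.00108695652173913,0.00108695652173913,0.00108695652173913,0.225,0.00108695652173913,0.00108695652173913,0.00108695652173913,0.00108695652173913,0.00108695652173913,0.00108695652173913,0.00108695652173913,0.00108695652173913,0.00108695652173913,0.00108695652173913,0.00108695652173913,0.00108695652173913,0.00108695652173913,0.00108695652173913,0.00108695652173913,0.00108695652173913,0.00108695652173913,0.00108695652173913,0.00108695652173913,0.00108695652173913,0.00108695652173913,0.00108695652173913,0.00108695652173913,0.00108695652173913,0.00108695652173913,0.00108695652173913,0.00108695652173913,0.00108695652173913,0.00108695652173913,0.00108695652173913,0.00108695652173913,0.00108695652173913,0.00108695652173913,0.00108695652173913,0.00108695652173913,0.00108695652173913,0.00108695652173913,0.00108695652173913,0.00108695652173913,0.00108695652173913,0.00108695652173913,0.00108695652173913,0.00108695652173913,0.00108695652173913,0.00108695652173913,0.00108695652173913,0.00108695652173913,0.00108695652173913,0.00108695652173913],"sig17_like":[0.00212765957446809,0.00212765957446809,0.00212765957446809,0.00212765957446809,0.00212765957446809,0.00212765957446809,0.00212765957446809,0.00212765957446809,0.00212765957446809,0.00212765957446809,0.00212765957446809,0.00212765957446809,0.00212765957446809,0.00212765957446809,0.00212765957446809,0.00212765957446809,0.00212765957446809,0.00212765957446809,0.00212765957446809,0.00212765957446809,0.00212765957446809,0.00212765957446809,0.00212765957446809,0.00212765957446809,0.00212765957446809,0.00212765957446809,0.00212765957446809,0.00212765957446809,0.00212765957446809,0.00212765957446809,0.00212765957446809,0.00212765957446809,0.00212765957446809,0.00212765957446809,0.00212765957446809,0.00212765957446809,0.00212765957446809,0.00212765957446809,0.00212765957446809,0.00212765957446809,0.00212765957446809,0.00212765957446809,0.00212765957446809,0.00212765957446809,0.00212765957446809,0.00212765957446809,0.00212765957446809,0.00212765957446809,0.00212765957446809,0.00212765957446809,0.00212765957446809,0.00212765957446809,0.00212765957446809,0.00212765957446809,0.00212765957446809,0.00212765957446809,0.00212765957446809,0.00212765957446809,0.00212765957446809,0.00212765957446809,0.00212765957446809,0.00212765957446809,0.00212765957446809,0.00212765957446809,0.00212765957446809,0.00212765957446809,0.00212765957446809,0.00212765957446809,0.00212765957446809,0.00212765957446809,0.00212765957446809,0.4,0.00212765957446809,0.00212765957446809,0.00212765957446809,0.00212765957446809,0.00212765957446809,0.00212765957446809,0.00212765957446809,0.00212765957446809,0.00212765957446809,0.00212765957446809,0.00212765957446809,0.00212765957446809,0.00212765957446809,0.00212765957446809,0.00212765957446809,0.4,0.00212765957446809,0.00212765957446809,0.00212765957446809,0.00212765957446809,0.00212765957446809,0.00212765957446809,0.00212765957446809,0.00212765957446809],"uniform":[0.0104166666666667,0.0104166666666667,0.0104166666666667,0.0104166666666667,0.0104166666666667,0.0104166666666667,0.0104166666666667,0.0104166666666667,0.0104166666666667,0.0104166666666667,0.0104166666666667,0.0104166666666667,0.0104166666666667,0.0104166666666667,0.0104166666666667,0.0104166666666667,0.0104166666666667,0.0104166666666667,0.0104166666666667,0.0104166666666667,0.0104166666666667,0.0104166666666667,0.0104166666666667,0.0104166666666667,0.0104166666666667,0.0104166666666667,0.0104166666666667,0.0104166666666667,0.0104166666666667,0.0104166666666667,0.0104166666666667,0.0104166666666667,0.0104166666666667,0.0104166666666667,0.0104166666666667,0.0104166666666667,0.0104166666666667,0.0104166666666667,0.0104166666666667,0.0104166666666667,0.0104166666666667,0.0104166666666667,0.0104166666666667,0.0104166666666667,0.0104166666666667,0.0104166666666667,0.0104166666666667,0.0104166666666667,0.0104166666666667,0.0104166666666667,0.0104166666666667,0.0104166666666667,0.0104166666666667,0.0104166666666667,0.0104166666666667,0.0104166666666667,0.0104166666666667,0.0104166666666667,0.0104166666666667,0.0104166666666667,0.0104166666666667,0.0104166666666667,0.0104166666666667,0.0104166666666667,0.0104166666666667,0.0104166666666667,0.0104166666666667,0.0104166666666667,0.0104166666666667,0.0104166666666667,0.0104166666666667,0.0104166666666667,0.0104166666666667,0.0104166666666667,0.0104166666666667,0.0104166666666667,0.0104166666666667,0.0104166666666667,0.0104166666666667,0.0104166666666667,0.0104166666666667,0.0104166666666667,0.0104166666666667,0.0104166666666667,0.0104166666666667,0.0104166666666667,0.0104166666666667,0.0104166666666667,0.0104166666666667,0.0104166666666667,0.0104166666666667,0.0104166666666667,0.0104166666666667,0.0104166666666667,0.0104166666666667,0.0104166666666667]}
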