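cohort	study	n_cases	n_controls
alzheimers	GSE4757	10	10
alzheimers	GSE48350	80	173
alzheimers	GSE5281	87	74
lung_cancer	GSE18842	46	45
lung_cancer	GSE102287	32	34
lung_cancer	GSE118370	6	6
lung_cancer	GSE19188	94	62
lung_cancer	GSE19804	60	60
lung_cancer	GSE103888	13	6
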