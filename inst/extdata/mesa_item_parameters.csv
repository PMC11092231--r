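item,label,occasion,class,loading,communality,alpha,alpha_se,delta,delta_se
i01,MPF consumption at breakfast,breakfast,MPF,0.54,0.30,1.10,0.14,-0.88,0.11
i10,MPF consumption at afternoon snack,afternoon_snack,MPF,0.50,0.25,0.98,0.11,-0.72,0.10
i16,MPF consumption at evening snack,evening_snack,MPF,0.52,0.27,1.04,0.12,-0.55,0.08
i04,MPF consumption at morning snack,morning_snack,MPF,0.55,0.30,1.11,0.12,-0.47,0.08
i05,PF consumption at morning snack,morning_snack,PF,0.38,0.14,0.70,0.12,-0.17,0.13
i06,UPF consumption at morning snack,morning_snack,UPF,0.63,0.39,1.37,0.14,0.14,0.06
i18,UPF consumption at evening snack,evening_snack,UPF,0.55,0.31,1.13,0.10,0.36,0.07
i09,UPF consumption at lunch,lunch,UPF,0.56,0.31,1.14,0.10,0.38,0.08
i15,UPF consumption at dinner,dinner,UPF,0.54,0.29,1.08,0.10,0.42,0.08
i12,UPF consumption at afternoon snack,afternoon_snack,UPF,0.45,0.20,0.85,0.08,0.62,0.11
i03,UPF consumption at breakfast,breakfast,UPF,0.51,0.26,1.01,0.09,0.75,0.11
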