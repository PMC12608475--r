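name,group,delta_d,delta_p,delta_hb
glucose,carbohydrates,18.6,17.5,22.0
fructose,carbohydrates,16.2,15.3,22.4
sucrose,carbohydrates,17.0,14.0,21.0
oleic acid,fats,16.2,2.8,6.2
triolein,fats,16.4,3.8,4.6
tripalmitin,fats,16.4,4.8,8.0
glycine,amino acids,17.5,13.5,19.0
leucine,amino acids,18.5,6.5,13.5
limonene,non-polar essential oil components,17.2,1.8,4.3
alpha-pinene,non-polar essential oil components,16.4,1.1,2.2
linalool,polar essential oil components,16.8,3.6,8.7
eugenol,polar essential oil components,19.0,4.5,9.0
alpha-tocopherol,vitamins,17.0,1.5,4.0
retinol,vitamins,17.5,4.0,5.5
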