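# Sociodemographic marginal counts of the 756 interviewed Dialog Partners
# in the countrywide Benin survey: counts per level of each covariate.
variable,level,count
zone,Sudanian,401
zone,Sudano-Guinean,299
zone,Guineo-Congolian,56
sex,men,359
sex,women,397
age_class,17-35,271
age_class,36-50,358
age_class,>50,127
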