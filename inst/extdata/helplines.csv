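name,phone,region,operational
Sneha,044-24640050,Chennai,true
Aasra,98204-66726,Mumbai,true
iCall,9152987821,Mumbai,true
Sumaitri,011-23389090,Delhi,true
Vandrevala Foundation,1860-2662-345,National,true
Kiran,1800-599-0019,National,true
Oldline,044-00000000,Chennai,false
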