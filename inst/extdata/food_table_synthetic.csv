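food_id,name,kcal_per_unit,category,ingredients
F001,oatmeal with banana,280,breakfast,oats;milk;banana;honey
F002,greek yogurt parfait,220,breakfast,yogurt;granola;berries;honey
F003,scrambled eggs on toast,330,breakfast,egg;bread;butter;salt
F004,blueberry pancakes,450,breakfast,flour;egg;milk;blueberry;syrup
F005,bagel with cream cheese,380,breakfast,bagel;cream cheese
F006,fruit smoothie,190,breakfast,banana;berries;yogurt;milk
F101,cheeseburger,550,main,bun;beef patty;cheese;lettuce;ketchup
F102,bacon burger,640,main,bun;beef patty;bacon;cheese;ketchup
F103,veggie burger,420,main,bun;bean patty;lettuce;tomato;mayo
F104,margherita pizza slice,290,main,dough;tomato sauce;mozzarella;basil
F105,pepperoni pizza slice,330,main,dough;tomato sauce;mozzarella;pepperoni
F106,chicken caesar salad,390,main,chicken;romaine;parmesan;crouton;caesar dressing
F107,garden salad,180,main,romaine;tomato;cucumber;carrot;vinaigrette
F108,turkey sandwich,360,main,bread;turkey;lettuce;tomato;mayo
F109,ham and cheese sandwich,410,main,bread;ham;cheese;butter
F110,chicken burrito,620,main,tortilla;chicken;rice;beans;cheese;salsa
F111,bean burrito,520,main,tortilla;rice;beans;cheese;salsa
F112,spaghetti bolognese,560,main,pasta;beef;tomato sauce;parmesan
F113,penne arrabbiata,480,main,pasta;tomato sauce;chili;garlic
F114,salmon with rice,510,main,salmon;rice;broccoli;soy sauce
F115,tofu stir fry,400,main,tofu;rice;broccoli;carrot;soy sauce
F116,chicken noodle soup,250,main,chicken;noodles;carrot;celery;broth
F117,lentil soup,230,main,lentils;carrot;celery;onion;broth
F118,sushi roll,310,main,rice;salmon;nori;avocado
F201,apple,80,snack,apple
F202,banana,105,snack,banana
F203,trail mix,240,snack,peanuts;raisins;chocolate
F204,chocolate chip cookie,210,snack,flour;butter;sugar;chocolate
F205,potato chips,160,snack,potato;oil;salt
F206,granola bar,150,snack,oats;honey;nuts
F207,carrot sticks with hummus,120,snack,carrot;hummus
F208,cheese and crackers,200,snack,cheese;crackers
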